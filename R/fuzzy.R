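#' @title Mamdani fuzzy inference for the gain-scheduling controller
#' @description Dual-input (temperature error `e`, error change `ec`),
#'   quad-output (`dKp`, `dKi`, `dKd`, `lambda`) Mamdani inference. Each
#'   universe carries seven triangular membership functions (NB, NM, NS, ZO,
#'   PS, PM, PB) with evenly spaced centers and 50 % overlap; rule activation
#'   is min (AND), aggregation is max, defuzzification is the centroid of the
#'   clipped-and-aggregated output sets.
#' @name fuzzy
NULL

FUZZY_LABELS <- c("NB", "NM", "NS", "ZO", "PS", "PM", "PB")

# normalized defuzzification grid: label k has center (k - 1) on [0, 6]
.fz_grid <- seq(0, 6, length.out = 601)
.fz_mf <- vapply(seq_len(7), function(k) pmax(0, 1 - abs(.fz_grid - (k - 1))),
                 numeric(length(.fz_grid)))

#' Construct a fuzzy universe
#'
#' @param lower,upper Bounds of the universe (lower < upper). The seven
#'   linguistic terms NB..PB have triangular membership functions with centers
#'   evenly spaced from `lower` to `upper`.
#' @return An object of class `fuzzy_universe`.
#' @examples
#' u <- fuzzy_universe(-3, 3)
#' fuzzify(0, u) # ZO has degree 1
#' @export
fuzzy_universe <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("fuzzy_universe: need finite lower < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper,
                 centers = seq(lower, upper, length.out = 7)),
            class = "fuzzy_universe")
}

#' Membership degrees of a crisp value
#'
#' Values outside the universe are clipped to its bounds, so an input beyond
#' the upper bound fires PB with degree 1. At most two terms are active and
#' their degrees sum to 1.
#'
#' @param x Crisp input.
#' @param universe A [fuzzy_universe()].
#' @return Named numeric vector of seven degrees in `[0, 1]`.
#' @export
fuzzify <- function(x, universe) {
  x <- min(max(x, universe$lower), universe$upper)
  # normalized position in [0, 6]; term k peaks at (k - 1)
  s <- (x - universe$lower) / (universe$upper - universe$lower) * 6
  mu <- pmax(0, 1 - abs(s - 0:6))
  names(mu) <- FUZZY_LABELS
  mu
}

#' Read a quad-output fuzzy rule table
#'
#' Parses the 7x7 rule grid from a CSV whose first column holds the `ec`
#' linguistic term of each row, whose header holds the `e` terms, and whose
#' cells carry the four output terms as `"dKp/dKi/dKd/lambda"` (e.g.
#' `"PB/NB/PS/PB"`). The table shipped with the package encodes the expert
#' rule base of the layer-house controller.
#'
#' @param path CSV path; default is the shipped rule base.
#' @return Object of class `fuzzy_rules`: a list of four 7x7 integer matrices
#'   (`dKp`, `dKi`, `dKd`, `lambda`), rows indexed by `ec` term, columns by
#'   `e` term, entries in 1..7 indexing NB..PB.
#' @export
fuzzy_rules <- function(path = system.file("extdata", "fuzzy_rules.csv",
                                           package = "coopclim")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(raw)[1], "ec") ||
      !identical(names(raw)[-1], FUZZY_LABELS) ||
      !identical(raw$ec, FUZZY_LABELS)) {
    stop("fuzzy_rules: table must be a 7x7 grid with NB..PB rows (ec) and ",
         "columns (e)", call. = FALSE)
  }
  chans <- c("dKp", "dKi", "dKd", "lambda")
  out <- lapply(chans, function(.) {
    matrix(NA_integer_, 7, 7, dimnames = list(ec = FUZZY_LABELS,
                                              e = FUZZY_LABELS))
  })
  names(out) <- chans
  for (i in 1:7) {
    for (j in 1:7) {
      cell <- strsplit(raw[i, j + 1], "/", fixed = TRUE)[[1]]
      if (length(cell) != 4 || !all(cell %in% FUZZY_LABELS)) {
        stop("fuzzy_rules: malformed cell at (", FUZZY_LABELS[i], ", ",
             FUZZY_LABELS[j], "): ", raw[i, j + 1], call. = FALSE)
      }
      for (c_ in 1:4) out[[c_]][i, j] <- match(cell[c_], FUZZY_LABELS)
    }
  }
  class(out) <- "fuzzy_rules"
  out
}

#' Fuzzy inference: aggregated output strengths
#'
#' Fires all rules with min (AND) activation of the two input memberships and
#' aggregates per output linguistic term with max, separately for each of the
#' four output channels.
#'
#' @param mu_e,mu_ec Membership vectors from [fuzzify()] for `e` and `ec`.
#' @param rules A [fuzzy_rules()] table (rows = `ec`, columns = `e`).
#' @return List of four named strength vectors (length 7) for `dKp`, `dKi`,
#'   `dKd`, `lambda`.
#' @export
fuzzy_infer <- function(mu_e, mu_ec, rules) {
  S <- outer(mu_ec, mu_e, pmin) # rows ec, cols e, matching the rule grid
  act <- which(S > 0)
  out <- lapply(rules, function(tab) {
    st <- numeric(7)
    for (cell in act) {
      lab <- tab[cell]
      if (S[cell] > st[lab]) st[lab] <- S[cell]
    }
    names(st) <- FUZZY_LABELS
    st
  })
  out
}

#' Centroid defuzzification
#'
#' Clips each output triangle at its aggregated strength, takes the pointwise
#' maximum, and returns the centroid of the resulting shape (computed on a
#' fixed 601-point grid over the universe). An all-zero strength vector
#' returns the universe midpoint with a warning.
#'
#' @param strengths Named length-7 strength vector (one per linguistic term).
#' @param universe A [fuzzy_universe()].
#' @return Crisp value inside the universe bounds.
#' @export
defuzzify <- function(strengths, universe) {
  mid <- (universe$lower + universe$upper) / 2
  act <- which(strengths > 0)
  if (!length(act)) {
    warning("defuzzify: all memberships zero; returning universe midpoint")
    return(mid)
  }
  agg <- rep(0, length(.fz_grid))
  for (k in act) agg <- pmax(agg, pmin(.fz_mf[, k], strengths[k]))
  cen_s <- sum(.fz_grid * agg) / sum(agg)
  universe$lower + (universe$upper - universe$lower) * cen_s / 6
}

#' Map the lambda-channel output onto [0, 1]
#'
#' The crisp lambda-channel value is mapped affinely so that a full-strength
#' NB output lands exactly at 0 and a full-strength PB output at 1 (the
#' anchors are the centroids of the pure NB and PB shapes on the channel
#' universe), then clipped to `[0, 1]`.
#'
#' @param value Defuzzified lambda-channel value.
#' @param universe The lambda-channel [fuzzy_universe()].
#' @return Split coefficient in `[0, 1]`.
#' @export
lambda_from_output <- function(value, universe) {
  anchors <- lambda_anchors(universe)
  lam <- (value - anchors[1]) / (anchors[2] - anchors[1])
  min(max(lam, 0), 1)
}

lambda_anchors <- function(universe) {
  one_hot <- function(k) { s <- numeric(7); s[k] <- 1; s }
  c(defuzzify(one_hot(1), universe), defuzzify(one_hot(7), universe))
}
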