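# shared fixtures: default config and small constant-driver builders

default_cfg <- house_config()

# a constant exogenous record (pad closed unless stated)
const_exo <- function(t0 = 20, ts = 15, irradiance = 0, tg = 22,
                      tn = NA_real_, tw = NA_real_, pad_open = FALSE) {
  list(t0 = t0, ts = ts, irradiance = irradiance, tg = tg,
       tn = tn, tw = tw, pad_open = pad_open)
}

# constant-driver data frame of n minutes
const_driver <- function(n, t0 = 20, ts = 15, irradiance = 0, tg = 22,
                         pad_open = FALSE) {
  data.frame(minute = seq_len(n) - 1, t0 = t0, ts = ts, rh = NA_real_,
             irradiance = irradiance, tg = tg, tn = NA_real_, tw = NA_real_,
             pad_open = pad_open)
}

# run the Euler loop to steady state under constant inputs
euler_settle <- function(exo, cmd, cfg, Ti0, steps = 600, dt = 60) {
  Ti <- Ti0
  for (i in seq_len(steps)) Ti <- plant_step(Ti, exo, cmd, cfg, dt)$Ti
  Ti
}
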