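# shared fixtures built in code

# exact samples of Y(t) = P + (100 - P) exp(-K t) on the default FLIP grid
exact_decay <- function(P, K, n = 70, dt = 4) {
  t <- (0:(n - 1)) * dt
  data.frame(time_s = t, percent = P + (100 - P) * exp(-K * t))
}

# a decay_fit with hand-set parameters (zero uncertainty unless given),
# for closed-form t75 / BI arithmetic
fixed_fit <- function(P, K, se_P = 0, se_K = 0, cov_PK = 0) {
  structure(list(plateau = P, K = K, se_plateau = se_P, se_K = se_K,
                 cov_PK = cov_PK, rss = 0, n_points = 70, converged = TRUE,
                 diagnostic = NA_character_, data = NULL),
            class = "decay_fit")
}

# independent step-by-step iteration of the FLIP recurrence (the oracle the
# simulator must match; written against the update definition, not the code)
flip_recurrence_oracle <- function(n_frames, b, x, a) {
  M <- B <- numeric(n_frames)
  M[1] <- B[1] <- 1000
  for (t in 1:(n_frames - 1)) {
    M[t + 1] <- (1 - a) * ((1 - b) * M[t] + x * (B[t] - M[t]))
    B[t + 1] <- (1 - a) * (B[t] - x * (B[t] - M[t]))
  }
  list(M = M, B = B)
}

# split a gen_flip_traces() table into the pieces normalize_traces() wants
split_traces <- function(traces, cell = NULL) {
  mothers <- traces[traces$role == "mother", ]
  if (is.null(cell)) cell <- mothers$cell_id[1]
  list(mother = traces[traces$role == "mother" & traces$cell_id == cell, ],
       bud = traces[traces$role == "bud" & traces$cell_id == cell, ],
       controls = split(traces[traces$role == "control", ],
                        traces$cell_id[traces$role == "control"]))
}
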