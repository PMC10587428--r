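# Independent numerical oracle: stiff ODE integration of the compartment
# system driven by a linearly interpolated plasma curve, via deSolve.
# Returns the tissue concentration C_t = C1 + C2 on the same grid.
ode_tissue_oracle <- function(K1, k2, k3, t_grid, cp_values,
                              rtol = 1e-10, atol = 1e-10) {
  cpf <- stats::approxfun(t_grid, cp_values, rule = 2)
  out <- deSolve::ode(
    y = c(C1 = 0, C2 = 0), times = t_grid,
    func = function(t, y, parms) {
      list(c(K1 * cpf(t) - (k2 + k3) * y[1], k3 * y[1]))
    },
    method = "lsoda", rtol = rtol, atol = atol)
  out[, "C1"] + out[, "C2"]
}

# Frame-average a fine-grid curve exactly as the package does, but written
# independently (plain loop, no shared helper).
oracle_frame_average <- function(z, t_grid_min, fs) {
  h <- t_grid_min[2] - t_grid_min[1]
  sapply(seq_len(nrow(fs)), function(k) {
    i0 <- round(fs$frame_start[k] / 60 / h) + 1
    i1 <- round(fs$frame_end[k] / 60 / h) + 1
    zz <- z[i0:i1]
    sum((zz[-1] + zz[-length(zz)]) / 2) * h /
      ((fs$frame_end[k] - fs$frame_start[k]) / 60)
  })
}

# relative error ignoring frames where the reference is essentially zero
max_rel_err <- function(a, ref) {
  keep <- abs(ref) > 1e-6 * max(abs(ref))
  max(abs(a[keep] - ref[keep]) / abs(ref[keep]))
}

default_aif <- function() feng_params()
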