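# shared helpers for the test suite

# breadth-first search connectivity of a bond graph
graph_connected <- function(N, bonds) {
  adj <- vector("list", N)
  for (e in seq_len(nrow(bonds))) {
    i <- bonds[e, 1]; j <- bonds[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(N); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  all(seen)
}

# total conservative energy (springs with strain-normalized constant + area
# penalty); used as the finite-difference oracle for the analytic forces
total_energy <- function(mesh, positions, ell_act = 0, params) {
  i <- mesh$bonds[, 1]; j <- mesh$bonds[, 2]
  d <- positions[j, , drop = FALSE] - positions[i, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  ell_act <- rep_len(ell_act, nrow(mesh$bonds))
  e_spring <- sum(0.5 * params$kappa / mesh$rest_length *
                    (r - mesh$rest_length - ell_act)^2)
  e_spring + area_energy(mesh, positions, params)
}

fd_gradient <- function(fun, x, h = 1e-6) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    g[k] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  g
}

# pre-relaxed 5-ring mesh (area pre-stress equilibrated), cached per session
relaxed_hex5 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mesh <- build_hexagonal_cell(5)
      cfg <- run_config(mesh, "rd", stimulus = list(mode = "none"),
                        duration = 2, dt = 1e-4, uniform_zeta = TRUE,
                        coupling = coupling_params(mech_params(mesh),
                                                   ell_V_scale = 0))
      tr <- run_experiment(cfg)
      S <- length(tr$times)
      mesh$positions <- cbind(tr$x[S, ], tr$y[S, ])
      cache <<- mesh
    }
    cache
  }
})
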