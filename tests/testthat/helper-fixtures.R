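# Shared small fixtures, built once per test run.

fx <- new.env()

fixture_head_model <- function(n_voxels = 60) {
  key <- paste0("hm", n_voxels)
  if (is.null(fx[[key]])) fx[[key]] <- head_model(n_voxels = n_voxels)
  fx[[key]]
}

fixture_leadfield <- function(n_voxels = 60) {
  key <- paste0("lf", n_voxels)
  if (is.null(fx[[key]]))
    fx[[key]] <- generate_leadfield(fixture_head_model(n_voxels))
  fx[[key]]
}

fixture_graph <- function() {
  if (is.null(fx$graph)) fx$graph <- build_neighbors(standard_montage_64())
  fx$graph
}

# small simulated participant shared across tests (50 Hz, 24 trials)
fixture_participant <- function() {
  if (is.null(fx$participant)) {
    cfg <- sim_config(n_per_group = 4, n_blocks = 1L, trials_per_block = 24,
                      sfreq = 50, seed = 42)
    fx$participant <- simulate_participant(cfg, "control",
                                           fixture_leadfield(), seed = 43)
  }
  fx$participant
}

# independently coded Legendre-series solution of the sphere-dipole problem;
# serves as the oracle for the closed-form leadfield
series_sphere_potential <- function(dip, mom, elec, R = 1, nmax = 300) {
  b <- sqrt(sum(dip^2))
  e <- elec / R
  if (b < 1e-14) return(3 * as.numeric(e %*% mom) / (4 * pi * R^2))
  f <- b / R
  r0 <- dip / b
  u <- pmin(pmax(as.numeric(e %*% r0), -1), 1)
  s <- sqrt(pmax(0, 1 - u^2))
  mr <- sum(mom * r0)
  mtv <- mom - mr * r0
  tv <- e - outer(u, r0)
  tn <- sqrt(rowSums(tv^2))
  mtc <- ifelse(tn > 1e-12, as.numeric(tv %*% mtv) / tn, 0)
  V <- numeric(length(u))
  Pprev <- rep(1, length(u)) # P_0
  Pcur <- u                  # P_1
  for (n in 1:nmax) {
    P1n <- ifelse(s > 1e-12, n * (Pprev - u * Pcur) / s, 0)
    V <- V + (2 * n + 1) / n * f^(n - 1) * (n * mr * Pcur + mtc * P1n)
    Pnext <- ((2 * n + 1) * u * Pcur - n * Pprev) / (n + 1)
    Pprev <- Pcur
    Pcur <- Pnext
  }
  V / (4 * pi * R^2)
}
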