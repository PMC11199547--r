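# Shared fixtures and independent oracles for the test suite.

.fixtures <- new.env(parent = emptyenv())

ref_record <- function() {
  list(patient_id = "ref", TK = 42.2, LL = 37.4, TH = 0.43, TW = 25.1,
       CoM_AP = 0.03, CoM_SI = 0.21)
}

ref_model <- function(mode = "Indiv") {
  key <- paste0("model_", mode)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- assemble_model(ref_record(), config = model_config(mode))
  }
  .fixtures[[key]]
}

# Reduced cohort run shared across test files (10 patients, all configs/cases).
smoke_run <- function() {
  if (is.null(.fixtures$smoke)) {
    .fixtures$smoke <- suppressWarnings(run_experiment(run_config(n = 10, seed = 42)))
  }
  .fixtures$smoke
}

# Study-scale run used by the acceptance checks (93 patients).
full_run <- function() {
  if (is.null(.fixtures$full)) {
    .fixtures$full <- suppressWarnings(run_experiment(run_config(n = 93, seed = 1)))
  }
  .fixtures$full
}

# A load case that deflects a single chosen joint by `deg`, for
# finite-difference checks of moment arms.
single_joint_case <- function(joint, deg) {
  part <- stats::setNames(numeric(1), joint)
  part[joint] <- 1
  structure(list(name = "single_joint", external_mass_kg = 0,
                 hand_lever_m = NA_real_, flexion_deg = deg,
                 sacral_fraction = 0, lumbar_fraction = 1,
                 lumbar_partition = part),
            class = "load_case")
}

# Independent brute-force solver for small static-optimization instances:
# eliminate the equality constraints through a null-space parameterization
# and minimize with constrOptim under the box constraints. `x0` must be a
# strictly interior feasible activation vector.
oracle_min_cubed <- function(G, d, x0) {
  n <- ncol(G)
  sv <- svd(G, nv = n)
  r <- sum(sv$d > 1e-12 * max(sv$d))
  N <- sv$v[, (r + 1):n, drop = FALSE]
  f <- function(z) sum((x0 + N %*% z)^3)
  g <- function(z) as.numeric(crossprod(N, 3 * (x0 + N %*% z)^2))
  ui <- rbind(N, -N)
  ci <- c(-x0, x0 - 1)
  fit <- stats::constrOptim(rep(0, ncol(N)), f, g, ui = ui, ci = ci,
                            control = list(reltol = 1e-14, maxit = 2000))
  x <- as.numeric(x0 + N %*% fit$par)
  list(x = x, objective = sum(x^3))
}
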