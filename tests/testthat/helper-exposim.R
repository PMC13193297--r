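# Shared fixtures and independent oracles used across the suite.

toy_hierarchy <- function(n = 3L, reach = 2L) {
  exposure_hierarchy(data.frame(
    position = seq_len(n),
    task_id = paste0("t", seq_len(n)),
    label = paste("task", seq_len(n))), reach = reach)
}

default_h <- function() load_hierarchy("shoe")

# Closed-form SUDS oracle for a task held continuously from t = 0 with entry
# level L: one point lost per full habituation interval, floored at 0.
# Independent of the engine's tick loop.
oracle_hold_suds <- function(L, t, interval = 120) {
  max(0, L - floor(t / interval))
}

# Literal brute-force Holm step-down, straight from the definition: at step i
# reject/adjust with factor (m - i + 1), enforcing monotonicity.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Marginal cell proportion of the logit-normal-binomial generator, by direct
# numerical integration over the latent subject effect.
oracle_marginal_prop <- function(mu, spec, subject_sd) {
  p0 <- (mu - spec$total_min) / (spec$total_max - spec$total_min)
  out <- vapply(as.vector(p0), function(pp) {
    stats::integrate(function(b) {
      stats::plogis(stats::qlogis(pp) + b) * stats::dnorm(b, 0, subject_sd)
    }, -Inf, Inf)$value
  }, numeric(1))
  if (is.matrix(mu)) matrix(out, nrow = nrow(mu), dimnames = dimnames(mu))
  else out
}

decision_choices <- function(log) {
  vapply(log_events(log, "decision_point"),
         function(ev) as.integer(ev$payload$choice), integer(1))
}

decision_times <- function(log) {
  vapply(log_events(log, "decision_point"), function(ev) ev$t, numeric(1))
}

tbes_only_config <- function(cell_means = default_cell_means()$tbes,
                             subject_sd = 0.6,
                             n_per_arm = c(hmd = 20L, desktop = 21L)) {
  generator_config(
    n_per_arm = n_per_arm,
    measures = measure_registry()["tbes"],
    cell_means = list(tbes = cell_means),
    subject_sd = subject_sd)
}

null_cell_means <- function(value = 21) {
  matrix(value, 2, 4,
         dimnames = list(c("hmd", "desktop"), c("T0", "T1", "T2", "T3")))
}
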