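#' Read a simulation scenario from a YAML configuration file
#'
#' The schema has top-level blocks `design`, `variance`, `policy` and the
#' scalars `theta`, `n_reps`, `seed`, `analysis_mode`. `design` holds `C`,
#' `P`, `m`, `cohort`, `X_init` (compact string or list of row strings),
#' `interim_periods`, `alpha`, `beta`, `delta`; `variance` holds the four
#' `sigma2_*` components (`sigma2_e` required); `policy` holds `w`, `eta`,
#' `gamma`, `restriction`. Unknown keys anywhere are rejected. Defaults:
#' policy w = 0.5, eta = 0, gamma = 2.5, restriction `"none"`; theta =
#' delta; n_reps = 10000; seed = 1; analysis_mode `"collapsed"`.
#'
#' @param path Path to the YAML (or JSON; parsed by yaml either way) file.
#' @return A validated `sw_scenario`.
#' @examples
#' cfg <- parse_config(system.file("extdata", "tds2.yaml", package = "raswcrt"))
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("design", "variance", "policy", "theta", "n_reps",
                    "seed", "analysis_mode"), "top level")
  if (is.null(raw$design) || is.null(raw$variance))
    stop("config must contain 'design' and 'variance' blocks")
  dd <- raw$design
  check_keys(dd, c("C", "P", "m", "cohort", "X_init", "interim_periods",
                   "alpha", "beta", "delta"), "design")
  need <- c("C", "P", "m", "X_init", "delta")
  miss <- setdiff(need, names(dd))
  if (length(miss)) stop("design block is missing: ", paste(miss, collapse = ", "))
  X <- if (length(dd$X_init) > 1) parse_allocation(paste(dd$X_init, collapse = ","))
  else parse_allocation(dd$X_init)
  design <- sw_design(C = dd$C, P = dd$P, m = dd$m,
                      cohort = dd$cohort %||% "cross_sectional",
                      X_init = X,
                      interim_periods = unlist(dd$interim_periods) %||% integer(0),
                      alpha = dd$alpha %||% 0.05, beta = dd$beta %||% 0.2,
                      delta = dd$delta)
  vv <- raw$variance
  check_keys(vv, c("sigma2_c", "sigma2_pi", "sigma2_s", "sigma2_e"), "variance")
  if (is.null(vv$sigma2_e)) stop("variance block is missing sigma2_e")
  vc <- sw_variance(sigma2_c = vv$sigma2_c %||% 0,
                    sigma2_pi = vv$sigma2_pi %||% 0,
                    sigma2_s = vv$sigma2_s %||% 0,
                    sigma2_e = vv$sigma2_e)
  pp <- raw$policy %||% list()
  check_keys(pp, c("w", "eta", "gamma", "restriction"), "policy")
  policy <- sw_policy(w = pp$w %||% 0.5, eta = pp$eta %||% 0,
                      gamma = pp$gamma %||% 2.5,
                      restriction = pp$restriction %||% "none")
  sw_scenario(design, vc, policy,
              theta = raw$theta %||% design$delta,
              n_reps = raw$n_reps %||% 10000,
              seed = raw$seed %||% 1,
              analysis_mode = raw$analysis_mode %||% "collapsed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Serialize a scenario back to YAML
#'
#' Inverse of [parse_config()]: `parse_config(write_config(cfg, path))`
#' reproduces the scenario.
#'
#' @param config An `sw_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  d <- config$design
  out <- list(
    design = list(C = d$C, P = d$P, m = d$m, cohort = d$cohort,
                  X_init = format_allocation(d$X_init),
                  interim_periods = as.list(d$interim_periods),
                  alpha = d$alpha, beta = d$beta, delta = d$delta),
    variance = unclass(config$vc)[c("sigma2_c", "sigma2_pi", "sigma2_s",
                                    "sigma2_e")],
    policy = list(w = config$policy$w, eta = config$policy$eta,
                  gamma = config$policy$gamma,
                  restriction = config$policy$restriction),
    theta = config$theta, n_reps = config$n_reps, seed = config$seed,
    analysis_mode = config$analysis_mode)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a result table with a reproducibility manifest
#'
#' Writes `df` as CSV and a JSON sidecar (`<path>.manifest.json`) holding
#' everything needed to reproduce the file: the full scenario configuration,
#' seed, package version, timestamp and the invoking command line.
#'
#' @param df Data frame of results.
#' @param path CSV output path.
#' @param config The `sw_scenario` (or NULL) the results came from.
#' @param extra Named list of additional manifest fields.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path, config = NULL, extra = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- c(list(
    package = "raswcrt",
    version = as.character(utils::packageVersion("raswcrt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = paste(commandArgs(), collapse = " "),
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) scenario_to_list(config) else NULL),
    extra)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

scenario_to_list <- function(config) {
  d <- config$design
  list(design = list(C = d$C, P = d$P, m = d$m, cohort = d$cohort,
                     X_init = format_allocation(d$X_init),
                     interim_periods = d$interim_periods,
                     alpha = d$alpha, beta = d$beta, delta = d$delta),
       variance = unclass(config$vc)[c("sigma2_c", "sigma2_pi", "sigma2_s",
                                       "sigma2_e")],
       policy = unclass(config$policy)[c("w", "eta", "gamma", "restriction")],
       theta = config$theta, n_reps = config$n_reps, seed = config$seed,
       analysis_mode = config$analysis_mode)
}

#' Sweep operating characteristics over a parameter grid
#'
#' Runs [sw_simulate()] for every combination of the supplied effect sizes
#' and policy parameters, reusing one information cache for the whole sweep
#' (information depends only on the design, never on theta, so theta is
#' iterated outermost at zero extra cost). Returns a tidy table with one row
#' per grid point.
#'
#' @param config Base `sw_scenario`.
#' @param theta,w,eta,gamma Vectors of values to sweep (defaults: the single
#'   value in `config`).
#' @param adaptive Passed to [sw_simulate()].
#' @param cache Shared information cache.
#' @param verbose Print one progress line per grid point?
#' @return Data frame with the grid coordinates, all operating
#'   characteristics and their Monte-Carlo standard errors.
#' @export
sw_sweep <- function(config, theta = config$theta, w = config$policy$w,
                     eta = config$policy$eta, gamma = config$policy$gamma,
                     adaptive = TRUE, cache = new_info_cache(),
                     verbose = interactive()) {
  grid <- expand.grid(gamma = gamma, eta = eta, w = w, theta = theta,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$theta <- grid$theta[g]
    cfg$policy$w <- grid$w[g]
    cfg$policy$eta <- grid$eta[g]
    cfg$policy$gamma <- grid$gamma[g]
    oc <- sw_simulate(cfg, adaptive = adaptive, cache = cache)
    if (verbose)
      message(sprintf("theta=%g w=%g eta=%g gamma=%g: ERP=%.4f EACP=%.3f",
                      cfg$theta, cfg$policy$w, cfg$policy$eta,
                      cfg$policy$gamma, oc$erp, oc$eacp))
    data.frame(theta = cfg$theta, w = cfg$policy$w, eta = cfg$policy$eta,
               gamma = cfg$policy$gamma, n_reps = oc$n_reps,
               erp = oc$erp, eacp = oc$eacp, esdcp = oc$esdcp,
               eb = oc$eb, ermse = oc$ermse,
               se_erp = oc$mc_se$erp, se_eacp = oc$mc_se$eacp,
               se_eb = oc$mc_se$eb)
  })
  do.call(rbind, rows)
}

#' Power curve and required sample size table
#'
#' Evaluates the fixed-design power over a range of per-cluster-period
#' sample sizes and reports the smallest m meeting the design's power
#' target.
#'
#' @param design An `sw_design`.
#' @param vc An `sw_variance`.
#' @param m_max Largest m tabulated (default: just past the required m).
#' @return A list with `required_m` and a data frame `curve` of (m, power).
#' @export
power_table <- function(design, vc, m_max = NULL) {
  req <- required_m(design, vc)
  if (is.null(m_max)) m_max <- req + 5L
  m <- seq_len(m_max)
  curve <- data.frame(m = m,
                      power = vapply(m, function(mm)
                        hh_power(design, vc, m = mm), numeric(1)))
  list(required_m = req, curve = curve)
}
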