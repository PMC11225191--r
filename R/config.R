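check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(x)
}

parse_oscillations <- function(osc_list) {
  if (is.data.frame(osc_list))   # JSON readers simplify the record list
    osc_list <- lapply(seq_len(nrow(osc_list)), function(i)
      as.list(osc_list[i, , drop = FALSE]))
  sigs <- list(rA = list(k = integer(), cos = numeric(), sin = numeric()),
               rB = list(k = integer(), cos = numeric(), sin = numeric()),
               gamma = list(k = integer(), cos = numeric(), sin = numeric()))
  for (o in osc_list) {
    check_keys(o, c("target", "k", "cos", "sin"), "environment$oscillations[]")
    if (is.null(o$target) || !o$target %in% names(sigs))
      stop("oscillation target must be one of rA, rB, gamma", call. = FALSE)
    k <- if (is.null(o$k)) 1L else as.integer(o$k)
    sigs[[o$target]]$k <- c(sigs[[o$target]]$k, k)
    sigs[[o$target]]$cos <- c(sigs[[o$target]]$cos,
                              if (is.null(o$cos)) 0 else o$cos)
    sigs[[o$target]]$sin <- c(sigs[[o$target]]$sin,
                              if (is.null(o$sin)) 0 else o$sin)
  }
  lapply(sigs, function(s) osc_signal(k = s$k, cos = s$cos, sin = s$sin))
}

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON (chosen by file extension) with sections
#' `preset` (a [scenario_preset()] name), `rates` (flat keys `r_A` ... `gamma`),
#' `environment` (`omega` plus a list of `oscillations`, each
#' `{target: rA|rB|gamma, k, cos, sin}`), `payoffs` (`xi`, `kappa`), `init`
#' (`p_A`, `N`) and `run` (`t_end`, `n_per_period`, `seed`, ...). Unknown keys
#' anywhere are a hard error; invariant violations are reported with the field
#' name. A `preset` supplies `rates` and `environment`; explicitly given
#' sections override it.
#'
#' @param path Path to the config file.
#' @return List with validated `rates` ([fixed_rates()]), `env`
#'   ([environment_spec()] or `NULL`), `payoffs` (`effective_payoffs` or
#'   `NULL`), `init`, `run`, `preset`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param raw A config structure already parsed from YAML/JSON.
#' @export
validate_config <- function(raw) {
  check_keys(raw, c("preset", "rates", "environment", "payoffs", "init", "run"),
             "config")
  rates <- NULL; env <- NULL
  if (!is.null(raw$preset)) {
    ps <- scenario_preset(raw$preset)
    rates <- ps$base; env <- ps$env
  }
  if (!is.null(raw$rates)) {
    rates <- rates_from_list(raw$rates)
    env <- NULL   # explicit rates invalidate a preset environment base
  }
  if (is.null(rates))
    stop("config must provide either 'preset' or 'rates'", call. = FALSE)
  if (!is.null(raw$environment)) {
    check_keys(raw$environment, c("omega", "oscillations"), "environment")
    omega <- raw$environment$omega
    if (is.null(omega)) stop("environment$omega is required", call. = FALSE)
    sigs <- parse_oscillations(raw$environment$oscillations)
    env <- environment_spec(rates, osc_rA = sigs$rA, osc_rB = sigs$rB,
                            osc_gamma = sigs$gamma, omega = omega)
  } else if (!is.null(env)) {
    env <- environment_spec(rates, osc_rA = env$osc_rA, osc_rB = env$osc_rB,
                            osc_gamma = env$osc_gamma, omega = env$omega)
  }
  payoffs <- NULL
  if (!is.null(raw$payoffs)) {
    check_keys(raw$payoffs, c("xi", "kappa"), "payoffs")
    payoffs <- payoffs_xk(raw$payoffs$xi, raw$payoffs$kappa)
  }
  init <- list(p_A = 0.5, N = 1)
  if (!is.null(raw$init)) {
    # YAML 1.1 readers resolve an unquoted key N to a boolean; undo that
    names(raw$init)[names(raw$init) == "FALSE"] <- "N"
    check_keys(raw$init, c("p_A", "N"), "init")
    if (!is.null(raw$init$p_A)) init$p_A <- raw$init$p_A
    if (!is.null(raw$init$N)) init$N <- raw$init$N
  }
  if (init$p_A < 0 || init$p_A > 1)
    stop("init$p_A must lie in [0, 1]", call. = FALSE)
  if (init$N < 0) stop("init$N must be non-negative", call. = FALSE)
  run <- list(t_end = 60, n_per_period = 40, seed = 1)
  if (!is.null(raw$run)) {
    check_keys(raw$run, c("t_end", "n_per_period", "seed", "Omega", "n_rep",
                          "gamma0"), "run")
    run[names(raw$run)] <- raw$run
  }
  list(rates = rates, env = env, payoffs = payoffs, init = init, run = run,
       preset = raw$preset)
}

#' Serialize a configuration
#'
#' Writes the explicit (preset-expanded) form of a configuration so that
#' `load_config(write_config(cfg, path))` reproduces the validated objects.
#'
#' @param cfg A validated config (from [load_config()] or [validate_config()]).
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  sig_rows <- function(sig, target) {
    if (!inherits(sig, "osc_signal") || !length(sig$k)) return(list())
    lapply(seq_along(sig$k), function(i)
      list(target = target, k = sig$k[i], cos = sig$cos[i], sin = sig$sin[i]))
  }
  out <- list(rates = as.list(cfg$rates))
  if (!is.null(cfg$env)) {
    osc <- c(sig_rows(cfg$env$osc_rA, "rA"), sig_rows(cfg$env$osc_rB, "rB"),
             sig_rows(cfg$env$osc_gamma, "gamma"))
    out$environment <- list(omega = cfg$env$omega, oscillations = osc)
  }
  if (!is.null(cfg$payoffs))
    out$payoffs <- list(xi = cfg$payoffs$xi, kappa = cfg$payoffs$kappa)
  out$init <- cfg$init
  out$run <- cfg$run
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(out, path)
  invisible(path)
}

#' Short digest of a configuration for output provenance
#'
#' FNV-1a hash (32-bit, hex) of the canonical deparse of the config; embedded
#' in report files so outputs can be traced to their exact inputs.
#'
#' @param cfg Any R object (typically a validated config).
#' @return 8-character hex string.
#' @export
config_digest <- function(cfg) {
  s <- paste(deparse(cfg, control = c("keepNA", "niceNames")), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 65536
    h <- (h - lo) + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply in split halves (doubles stay exact)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%08x", h)
}
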