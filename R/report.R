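#' One-row table form of a regime report
#'
#' @param report A `regime_report` from [classify_region()] or
#'   [classify_environment()].
#' @return One-row data.frame with columns `region`, `symbiosis`, `synergy`,
#'   `N_c_star`, `N_f_star`, `p_A_star`, `swapped` (plus `xi`, `kappa` when the
#'   report carries payoffs).
#' @export
regime_to_row <- function(report) {
  stopifnot(inherits(report, "regime_report"))
  row <- data.frame(region = report$region, symbiosis = report$symbiosis,
                    synergy = report$synergy, N_c_star = report$N_c_star,
                    N_f_star = report$N_f_star, p_A_star = report$p_A_star,
                    swapped = report$swapped, stringsAsFactors = FALSE)
  pay <- attr(report, "payoffs")
  if (!is.null(pay)) {
    row <- cbind(data.frame(xi = pay$xi, kappa = pay$kappa), row)
  }
  row
}

#' Phase-plane scan over a rectangular payoff grid
#'
#' Classifies every node of a uniform `(xi, kappa)` grid for fixed base
#' parameters; long-format output suitable for drawing the region map.
#'
#' @param r_A,r_B,a Base parameters (equal competition rates, balanced average
#'   gene transfer).
#' @param xi_range,kappa_range Length-2 numeric ranges.
#' @param n_xi,n_kappa Grid sizes.
#' @return data.frame with columns `xi`, `kappa`, `region`, `symbiosis`,
#'   `synergy`, `N_c_star`.
#' @export
phase_scan <- function(r_A, r_B, a, xi_range, kappa_range,
                       n_xi = 50, n_kappa = 50) {
  xi_v <- seq(xi_range[1], xi_range[2], length.out = n_xi)
  ka_v <- seq(kappa_range[1], kappa_range[2], length.out = n_kappa)
  grid <- expand.grid(xi = xi_v, kappa = ka_v, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- classify_region(r_A, r_B, a, grid$xi[i], grid$kappa[i])
    data.frame(xi = grid$xi[i], kappa = grid$kappa[i], region = r$region,
               symbiosis = r$symbiosis, synergy = r$synergy,
               N_c_star = r$N_c_star, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a result table with provenance
#'
#' Deterministic column order, 12 significant digits for floats, and the
#' config digest embedded as a comment line (CSV/TSV) or field (JSON).
#'
#' @param df data.frame to write.
#' @param path Output path; format from extension (`.csv`, `.tsv`, `.json`).
#' @param digest Optional provenance string (see [config_digest()]).
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, digest = NULL) {
  fmt_num <- function(x) if (is.double(x)) signif(x, 12) else x
  df[] <- lapply(df, fmt_num)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(config_digest = digest, rows = df), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(digest)) writeLines(paste0("# config_digest=", digest), con)
    utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
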