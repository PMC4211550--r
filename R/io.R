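#' Write a run's daily time series to CSV
#'
#' One row per day with the community-level series plus per-substrate C pools
#' and per-taxon biomass columns — the raw material for substrate-dynamics
#' and taxon-abundance figures.
#'
#' @param run a \code{dement_run}.
#' @param path output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_run_csv <- function(run, path) {
  st <- substrate_table()$substrate
  sub <- as.data.frame(t(run$substrate_C))
  names(sub) <- paste0("subC_", st[seq_len(nrow(run$substrate_C))])
  tax <- as.data.frame(t(run$taxon_biomass))
  names(tax) <- paste0("biomass_taxon_", seq_len(nrow(run$taxon_biomass)))
  df <- cbind(run$series, sub, tax)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Run summary as canonical JSON
#'
#' Scalar summaries plus run metadata, serialized deterministically: two
#' invocations with the same seed and configuration produce byte-identical
#' output.
#'
#' @param run a \code{dement_run}.
#' @param path optional path; when given the JSON is also written there.
#' @return JSON string (invisibly when \code{path} is given).
#' @export
run_summary_json <- function(run, path = NULL) {
  x <- c(list(seed = run$seed, T = run$T, days = run$days,
              scenario = run$scenario, m_E = run$m_E, m_U = run$m_U),
         run$scalars)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write paired-experiment outputs
#'
#' The per-pair table goes to \code{<prefix>_pairs.csv} and the t-test and
#' regression statistics to \code{<prefix>_stats.json}.
#'
#' @param paired a \code{dement_paired}.
#' @param prefix output path prefix.
#' @return Named vector of the two written paths, invisibly.
#' @export
write_paired_results <- function(paired, prefix) {
  csv <- paste0(prefix, "_pairs.csv")
  js <- paste0(prefix, "_stats.json")
  utils::write.csv(paired$pairs, csv, row.names = FALSE)
  stats <- list(
    scenario = paired$scenario, seed = paired$seed,
    n_pairs = paired$n_pairs, T_low = paired$T_low, T_high = paired$T_high,
    days = paired$days, m_E = paired$m_E, m_U = paired$m_U,
    mean_d_cue = mean(paired$pairs$d_cue, na.rm = TRUE),
    t_tests = paired$t_tests,
    regressions = paired$regressions
  )
  writeLines(jsonlite::toJSON(stats, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), js)
  invisible(c(pairs = csv, stats = js))
}
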