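#' Read study pairs from the standard CSV schema
#'
#' The schema has one row per treatment: columns `study_id`, `arm` (one of
#' `control` — the unstressed concentration-0 control, `env_only` — the
#' environment-only treatment, `tox` — toxicant alone, `tox_env` — toxicant
#' plus environmental stress), `concentration`, and either `survival` (a
#' fraction) or the count pair `n_total`/`n_survived`. UTF-8, header
#' required. Counts are converted to fractions and carried as weights.
#'
#' @param path Path to a CSV file.
#' @return A named list of [study_pair()] objects, one per `study_id`.
#' @export
read_study_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("study_id", "arm", "concentration")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  has_counts <- all(c("n_total", "n_survived") %in% names(df))
  if (!has_counts && !"survival" %in% names(df))
    stop("need either a 'survival' column or both 'n_total' and 'n_survived'",
         call. = FALSE)
  df$.row <- seq_len(nrow(df)) + 1L  # header is line 1
  if (has_counts) {
    have <- is.finite(df$n_total) | is.finite(df$n_survived)
    bad <- which(have & (!is.finite(df$n_total) | !is.finite(df$n_survived) |
                           df$n_total <= 0 | df$n_survived < 0 |
                           df$n_survived > df$n_total))
    if (length(bad))
      stop("invalid counts (need 0 <= n_survived <= n_total) in row(s): ",
           paste(df$.row[bad], collapse = ", "), call. = FALSE)
    if (!"survival" %in% names(df)) df$survival <- NA_real_
    df$survival[have] <- df$n_survived[have] / df$n_total[have]
    if (any(!have) && anyNA(df$survival[!have]))
      stop("rows without counts must provide 'survival': row(s) ",
           paste(df$.row[!have & is.na(df$survival)], collapse = ", "),
           call. = FALSE)
    has_counts <- all(have)
  }
  bad <- which(!is.finite(df$survival) | df$survival < 0 | df$survival > 1)
  if (length(bad))
    stop("survival outside [0, 1] in row(s): ",
         paste(df$.row[bad], collapse = ", "), call. = FALSE)
  bad_arm <- which(!df$arm %in% c("control", "env_only", "tox", "tox_env"))
  if (length(bad_arm))
    stop("unknown arm (expected control/env_only/tox/tox_env) in row(s): ",
         paste(df$.row[bad_arm], collapse = ", "), call. = FALSE)
  dup <- which(duplicated(df[, c("study_id", "arm", "concentration")]))
  if (length(dup))
    stop("duplicate (study_id, arm, concentration) in row(s): ",
         paste(df$.row[dup], collapse = ", "), call. = FALSE)

  build_arm <- function(sub, control_rows, study, arm_label) {
    if (nrow(control_rows) != 1L)
      stop(sprintf("study '%s': need exactly one %s row", study,
                   if (arm_label == "tox") "control" else "env_only"),
           call. = FALSE)
    if (nrow(sub) < 2L)
      stop(sprintf("study '%s': arm '%s' needs at least 2 concentrations",
                   study, arm_label), call. = FALSE)
    if (has_counts)
      dose_response_data(sub$concentration, n_total = sub$n_total,
                         n_survived = sub$n_survived,
                         control_survival = control_rows$survival,
                         control_n = control_rows$n_total)
    else
      dose_response_data(sub$concentration, sub$survival,
                         control_survival = control_rows$survival)
  }
  pairs <- lapply(split(df, df$study_id), function(sd) {
    study <- sd$study_id[1L]
    tox <- build_arm(sd[sd$arm == "tox", , drop = FALSE],
                     sd[sd$arm == "control", , drop = FALSE], study, "tox")
    comb <- build_arm(sd[sd$arm == "tox_env", , drop = FALSE],
                      sd[sd$arm == "env_only", , drop = FALSE], study, "tox_env")
    study_pair(study, tox, comb)
  })
  pairs[order(names(pairs))]
}

#' Serialise study pairs to the standard CSV schema
#'
#' The inverse of [read_study_csv()]; used by the `simulate` CLI
#' subcommand. Output is deterministic (fixed row and column order).
#'
#' @param pairs A list of [study_pair()] objects or a
#'   [generate_meta_dataset()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_study_csv <- function(pairs, path) {
  if (inherits(pairs, "sam_meta_dataset")) pairs <- pairs$pairs
  if (inherits(pairs, "study_pair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    arm_rows <- function(arm, label) {
      n <- arm$weights
      counts <- !is.null(arm$control_n) && all(n >= 1) && all(n == round(n))
      rbind(
        data.frame(study_id = p$study_id,
                   arm = if (label == "tox") "control" else "env_only",
                   concentration = 0,
                   n_total = if (counts) arm$control_n else NA_real_,
                   n_survived = if (counts)
                     round(arm$control_survival * arm$control_n) else NA_real_,
                   survival = arm$control_survival),
        data.frame(study_id = p$study_id, arm = label,
                   concentration = arm$concentrations,
                   n_total = if (counts) n else NA_real_,
                   n_survived = if (counts) round(arm$survival * n) else NA_real_,
                   survival = arm$survival))
    }
    rbind(arm_rows(p$tox_arm, "tox"), arm_rows(p$combined_arm, "tox_env"))
  })
  write_results(do.call(rbind, rows), path)
}

#' Write a results table as deterministic CSV
#'
#' Fixed column order (as given), floats formatted at 6 significant
#' digits, UTF-8, no row names — so a fixed input yields a byte-identical
#' file across runs and platforms.
#'
#' @param records A `data.frame` (may have zero rows: a header-only file is
#'   written).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                          sprintf("%.6g", out[[nm]]))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
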