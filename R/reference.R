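#' Bundled five-subject reference study tables
#'
#' The package ships the result tables of a five-subject cue-paced pedaling
#' study (16 trials x 5 cycles per subject, 32-channel EEG) as plain-text
#' data: the full offline WD grids for both window types, the pseudo-online
#' WD grids restricted to each subject's two best algorithms, and the metric
#' rows (TPR, FP/min, Acc) of the selected best models. They serve as worked
#' examples and as fixed inputs for regression-testing the WD arithmetic and
#' the selection procedures; they are *inputs*, not outputs, of this package.
#'
#' @name reference_tables
NULL

.ref_file <- function(name) {
  system.file("extdata", name, package = "pedalbci", mustWork = TRUE)
}

#' Reference offline WD grids
#'
#' @param window_type `"4s"` or `"2s"`.
#' @return Named list of five 8 x 5 [wd_matrix()] objects (subjects
#'   `"1"`..`"5"`).
#' @rdname reference_tables
#' @export
reference_wd_offline <- function(window_type = c("4s", "2s")) {
  window_type <- match.arg(window_type)
  df <- data.table::fread(.ref_file("study_wd_offline.tsv"), sep = "\t")
  df <- df[df$window == window_type, ]
  out <- lapply(split(df, df$subject), function(s) {
    m <- as.matrix(s[, c("A", "B", "C", "D", "E"), with = FALSE])
    rownames(m) <- as.character(s$config)
    wd_matrix(m, subject = as.character(s$subject[1]), mode = "offline",
              window_type = window_type)
  })
  out[order(as.integer(names(out)))]
}

#' Reference pseudo-online WD grids (two best algorithms per subject)
#'
#' @return Named list of five 8 x 2 [wd_matrix()] objects.
#' @rdname reference_tables
#' @export
reference_wd_pseudo_best2 <- function() {
  df <- data.table::fread(.ref_file("study_wd_pseudo_best2.tsv"), sep = "\t")
  out <- lapply(split(df, df$subject), function(s) {
    algs <- unique(s$algorithm)
    m <- vapply(algs, function(a) s$wd[s$algorithm == a],
                numeric(length(unique(s$config))))
    rownames(m) <- as.character(unique(s$config))
    wd_matrix(m, subject = as.character(s$subject[1]),
              mode = "pseudo-online", window_type = "4s")
  })
  out[order(as.integer(names(out)))]
}

#' Reference best-model metric rows
#'
#' @param mode `"offline"` or `"pseudo-online"`.
#' @return data.frame with `subject`, `algorithm`, `config`, `tpr_pct`,
#'   `fp_per_min`, `acc_pct` (plus cross-validation / cross-trial standard
#'   deviations).
#' @rdname reference_tables
#' @export
reference_best_models <- function(mode = c("offline", "pseudo-online")) {
  mode <- match.arg(mode)
  df <- data.table::fread(.ref_file("study_best_models.tsv"), sep = "\t")
  as.data.frame(df[df$mode == mode, ])
}

#' Reference uniform-model metric rows
#'
#' @param procedure `"uniform-algorithm"` (fixed algorithm, personalized
#'   configuration) or `"uniform-all"` (fixed algorithm and configuration).
#' @return data.frame of per-subject metric rows.
#' @rdname reference_tables
#' @export
reference_uniform_models <- function(procedure = c("uniform-algorithm",
                                                   "uniform-all")) {
  procedure <- match.arg(procedure)
  df <- data.table::fread(.ref_file("study_uniform_models.tsv"), sep = "\t")
  as.data.frame(df[df$procedure == procedure, ])
}
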