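#' Electrode configurations
#'
#' Loads the eight studied electrode configurations (channel subsets over the
#' sensorimotor area) from a `montages.tsv` file with columns `config_id`,
#' `name` and comma-separated `channels`. The bundled default covers: 1
#' motor+premotor (9 electrodes), 2 motor (5), 3 premotor (4), 4/6 left/right
#' motor+premotor (4), 5/7 left/right motor+premotor+medial (6), and 8 a
#' reduced motor+premotor set (5). Users can substitute their own layouts.
#'
#' @param file Path to a montage table; default is the bundled one.
#' @return Named list of configurations, each a list
#'   `(id, name, channels)`; names are the config ids as characters.
#' @export
electrode_configurations <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "montages.tsv", package = "pedalbci",
                        mustWork = TRUE)
  df <- data.table::fread(file, sep = "\t", colClasses = list(
    character = c("name", "channels")))
  if (anyDuplicated(df$config_id)) stop("montage file: duplicate config ids")
  out <- lapply(seq_len(nrow(df)), function(i) {
    ch <- trimws(strsplit(df$channels[i], ",")[[1]])
    if (length(ch) == 0) stop("montage file: empty configuration ",
                              df$config_id[i])
    bad <- setdiff(ch, .MONTAGE_32)
    if (length(bad))
      stop("montage file: unknown channel(s) ", paste(bad, collapse = ", "))
    list(id = as.integer(df$config_id[i]), name = df$name[i], channels = ch)
  })
  names(out) <- as.character(df$config_id)
  out
}

#' Electrode counts per configuration
#'
#' @param configs Output of [electrode_configurations()].
#' @return Named integer vector: configuration id -> number of electrodes.
#' @export
config_sizes <- function(configs = electrode_configurations()) {
  vapply(configs, function(cf) length(cf$channels), integer(1))
}

#' Look up one electrode configuration by id
#' @param id Configuration id (1-8 in the default table).
#' @param configs Output of [electrode_configurations()].
#' @return The configuration list.
#' @export
get_configuration <- function(id, configs = electrode_configurations()) {
  key <- as.character(id)
  if (!key %in% names(configs))
    stop("unknown electrode configuration: ", id)
  configs[[key]]
}

#' Restrict an epoch to one electrode configuration
#'
#' @param ep An [epoch()] containing all channels of the configuration.
#' @param config A configuration from [electrode_configurations()] (or an id).
#' @param configs Configuration table used when `config` is an id.
#' @return The epoch restricted to the configuration's channels, in the
#'   configuration's order; sample values are untouched.
#' @export
select_channels <- function(ep, config, configs = electrode_configurations()) {
  if (!is.list(config)) config <- get_configuration(config, configs)
  idx <- match(config$channels, ep$channel_names)
  if (anyNA(idx))
    stop("select_channels: epoch is missing channel(s) ",
         paste(config$channels[is.na(idx)], collapse = ", "))
  epoch(ep$samples[idx, , drop = FALSE], config$channels, ep$sampling_rate,
        ep$start_time)
}
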