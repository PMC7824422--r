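# Epochs container: the on-disk unit passed between pipeline stages.
# Layout mirrors a hierarchical scientific container (data / time_ms /
# labels / condition / kept_mask / attrs with fs, config hash, seed,
# package version); physically it is base-R serialization, which gives a
# bit-exact round trip with no external binary dependency.

#' Write an epochs container
#'
#' @param epochs an \code{eeg_epochs} object
#' @param path output file path (conventionally .epo)
#' @param provenance named list merged into the container attrs (e.g.
#'   config_hash, seed)
#' @return invisibly, \code{path}
#' @export
write_epochs <- function(epochs, path, provenance = list()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  obj <- list(
    data = epochs$data,
    time_ms = epochs$time_ms,
    labels = epochs$labels,
    condition = epochs$condition,
    kept_mask = epochs$kept_mask,
    attrs = c(list(fs = epochs$fs,
                   package_version =
                     as.character(utils::packageVersion("erspconn"))),
              provenance))
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Read an epochs container
#'
#' @param path file written by \code{\link{write_epochs}}
#' @return an \code{eeg_epochs} object; container attrs are attached as
#'   the \code{"attrs"} attribute
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop_data("no such epochs container: %s", path)
  obj <- readRDS(path)
  need <- c("data", "time_ms", "labels", "condition", "kept_mask", "attrs")
  if (!all(need %in% names(obj)))
    stop_data("not an epochs container: %s", path)
  ep <- eeg_epochs(obj$data, obj$attrs$fs, obj$labels,
                   time_ms = obj$time_ms, condition = obj$condition,
                   kept_mask = obj$kept_mask)
  attr(ep, "attrs") <- obj$attrs
  ep
}

#' Export band-by-window summaries as a TSV table
#'
#' Long format with columns subject, condition, channel, band, window,
#' value_db; UTF-8, tab-delimited, header row.
#'
#' @param summaries nested list: \code{summaries[[subject]][[condition]]}
#'   is a \code{band_window_summary}
#' @param path output TSV path
#' @return invisibly, the data.frame written
#' @export
export_band_window_tsv <- function(summaries, path) {
  rows <- list()
  for (s in seq_along(summaries)) {
    for (cond in names(summaries[[s]])) {
      bw <- summaries[[s]][[cond]]
      v <- bw$values
      dn <- dimnames(v)
      for (b in seq_len(dim(v)[2]))
        for (w in seq_len(dim(v)[3]))
          rows[[length(rows) + 1]] <- data.frame(
            subject = s, condition = cond, channel = dn[[1]],
            band = dn[[2]][b], window = dn[[3]][w],
            value_db = v[, b, w])
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}

#' Export ER-ciCOH seed maps as a TSV table
#'
#' Columns subject, condition, band, electrode, value.
#'
#' @param maps list of \code{er_cicoh_map}, one per subject
#' @param path output TSV path
#' @return invisibly, the data.frame written
#' @export
export_er_cicoh_tsv <- function(maps, path) {
  rows <- list()
  for (s in seq_along(maps)) {
    v <- maps[[s]]$values
    dn <- dimnames(v)
    for (cond in dn[[3]])
      for (b in dn[[2]])
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, condition = cond, band = b, electrode = dn[[1]],
          value = v[, b, cond])
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}
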