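#' @include AllClasses.R
NULL

.checkColumns <- function(df, cols, file) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(miss, collapse = ", ")))
}

#' Read spike trains from CSV
#'
#' Expects columns \code{neuron_id} and \code{t} (seconds). Malformed rows are
#' reported by number.
#'
#' @param file CSV path.
#' @param span optional recording span; defaults to \code{c(0, max(t))}.
#' @return A \linkS4class{SpikeTrainSet}.
#' @export
readSpikes <- function(file, span = NULL) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  .checkColumns(df, c("neuron_id", "t"), file)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$t))))
  if (length(bad))
    stop(sprintf("%s: non-numeric spike time at data row %d", file, bad[1]))
  df$t <- as.numeric(df$t)
  ids <- sort(unique(as.character(df$neuron_id)))
  times <- lapply(ids, function(id) sort(df$t[df$neuron_id == id]))
  SpikeTrainSet(times, span = span, ids = ids)
}

#' Write spike trains to CSV
#'
#' @param spikes a \linkS4class{SpikeTrainSet}.
#' @param file CSV path.
#' @export
writeSpikes <- function(spikes, file) {
  df <- data.frame(
    neuron_id = rep(spikes@ids, lengths(spikes@times)),
    t = unlist(spikes@times, use.names = FALSE))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read behavioral tracking from CSV
#'
#' Expects columns \code{t}, \code{x}, \code{y} and optionally \code{hd}
#' (radians).
#'
#' @param file CSV path.
#' @return A \linkS4class{TrajectorySample}; head direction, when present, is
#'   attached as attribute \code{hd}.
#' @export
readTracking <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  .checkColumns(df, c("t", "x", "y"), file)
  tr <- TrajectorySample(t = df$t, x = df$x, y = df$y)
  if ("hd" %in% colnames(df)) attr(tr, "hd") <- df$hd
  tr
}

#' Write behavioral tracking to CSV
#'
#' @param traj a \linkS4class{TrajectorySample}.
#' @param file CSV path.
#' @export
writeTracking <- function(traj, file) {
  write.csv(data.frame(t = traj@t, x = traj@x, y = traj@y,
                       speed = traj@speed, hd = traj@heading),
            file, row.names = FALSE)
  invisible(file)
}

#' Write a barcode to JSON
#'
#' Bars are serialized as records with dim, birth, death, lifetime and, when
#' thresholds are attached, a significance flag.
#'
#' @param b a \linkS4class{Barcode}.
#' @param file JSON path.
#' @export
writeBarcode <- function(b, file) {
  stopifnot(is(b, "Barcode"))
  bars <- b@bars
  th <- b@shuffleThresholds
  if (length(th) && any(!is.na(th))) {
    thr <- th[as.character(bars$dim)]
    bars$significant <- !is.finite(bars$death) |
      (!is.na(thr) & bars$lifetime > thr)
  }
  payload <- list(metric = b@metric, modulus = b@modulus,
                  threshold = b@threshold,
                  shuffle_thresholds = as.list(th), bars = bars)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' Write decoded toroidal coordinates to CSV
#'
#' Columns: t, theta1..thetaN, valid.
#'
#' @param coords a \linkS4class{ToroidalCoordinates}.
#' @param file CSV path.
#' @export
writeCoords <- function(coords, file) {
  stopifnot(is(coords, "ToroidalCoordinates"))
  df <- as.data.frame(coords@angles)
  colnames(df) <- paste0("theta", seq_len(ncol(df)))
  df <- cbind(t = coords@t, df, valid = coords@valid)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read decoded toroidal coordinates from CSV
#'
#' @param file CSV written by \code{\link{writeCoords}}.
#' @return A \linkS4class{ToroidalCoordinates} (without distributions).
#' @export
readCoords <- function(file) {
  df <- read.csv(file)
  .checkColumns(df, c("t", "theta1", "valid"), file)
  ang <- as.matrix(df[, grep("^theta", colnames(df)), drop = FALSE])
  new("ToroidalCoordinates", angles = ang %% (2 * pi), t = df$t,
      valid = as.logical(df$valid), distributions = list(),
      nBins = 16L)
}

#' Read a parameter profile from YAML
#'
#' Recognized keys match the arguments of \code{\link{parameterProfile}};
#' unknown keys are rejected.
#'
#' @param file YAML path.
#' @return A \linkS4class{ParameterProfile}.
#' @export
readProfile <- function(file) {
  y <- yaml::read_yaml(file)
  known <- names(formals(parameterProfile))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop(sprintf("%s: unknown profile key(s) %s", file,
                 paste(bad, collapse = ", ")))
  do.call(parameterProfile, y)
}

#' Write a parameter profile to YAML
#'
#' @param profile a \linkS4class{ParameterProfile}.
#' @param file YAML path.
#' @export
writeProfile <- function(profile, file) {
  stopifnot(is(profile, "ParameterProfile"))
  vals <- sapply(slotNames(profile), function(s) slot(profile, s),
                 simplify = FALSE)
  yaml::write_yaml(vals, file)
  invisible(file)
}

# small polynomial hash of a deparsed object, for provenance stamps
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
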