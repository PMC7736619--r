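#' Default in vitro protocols
#'
#' Each probe contributes three flow-cell datasets: dopamine varied 0-4500
#' nM in 50 nM steps, serotonin varied 0-4500 nM in 50 nM steps, and pH
#' varied 6.9-7.8 in 0.1 steps. Each concentration level is held for a
#' dwell period of `dwell` consecutive sweeps and the whole ladder is
#' repeated `replicates` times. Downstream training sampling is restricted
#' to the third quarter of each level's dwell timeline (to emulate the
#' avoidance of equilibration and flow artifacts), so the defaults are
#' sized to leave at least the per-probe sampling budget (2500 DA, 2500
#' 5-HT, 500 pH rows) in that quarter.
#'
#' @param analyte `"DA"`, `"5HT"` or `"pH"`.
#' @param min,max,step Concentration ladder (nM for DA/5-HT, pH units).
#' @param replicates Number of passes over the ladder.
#' @param dwell Sweeps recorded per level per pass.
#' @return A protocol list.
#' @export
invitro_protocol <- function(analyte = c("DA", "5HT", "pH"),
                             min = NULL, max = NULL, step = NULL,
                             replicates = NULL, dwell = 40) {
  analyte <- match.arg(analyte)
  def <- switch(analyte,
    DA = list(min = 0, max = 4500, step = 50, replicates = 3),
    `5HT` = list(min = 0, max = 4500, step = 50, replicates = 3),
    pH = list(min = 6.9, max = 7.8, step = 0.1, replicates = 5))
  p <- list(analyte = analyte,
            min = min %||% def$min, max = max %||% def$max,
            step = step %||% def$step,
            replicates = replicates %||% def$replicates,
            dwell = dwell)
  if (p$step <= 0) stop("step must be positive", call. = FALSE)
  if (p$max < p$min) stop("max must be >= min", call. = FALSE)
  if (p$dwell < 4) stop("dwell must be at least 4 sweeps", call. = FALSE)
  p
}

# Quarter index 1..4 for position idx (1-based) within a dwell block.
dwell_quarter <- function(idx, dwell) {
  pmin(4L, as.integer(floor((idx - 1) * 4 / dwell)) + 1L)
}

#' Generate one probe's in vitro dataset for one analyte protocol
#'
#' Simulates the flow-cell timeline: the analyte ladder is swept
#' `replicates` times, each level held for `dwell` sweeps at the waveform's
#' repetition period. Every sweep is tagged with the quarter of its level's
#' dwell timeline so the third-quarter sampling rule can be enforced when
#' the training pool is assembled. Non-varied analytes sit at baseline
#' (0 nM, pH 7.4).
#'
#' @param probe A [sample_probe_model()] result.
#' @param protocol An [invitro_protocol()].
#' @param seed Seed for measurement noise.
#' @return An `invitro_dataset`: `current` (n_sweeps x sweep_samples),
#'   `labels` (data.frame DA/`5HT`/pH), `time`, `quarter`, `level`,
#'   `analyte`, `probe_id`, `waveform`.
#' @export
generate_invitro_dataset <- function(probe, protocol, seed = 1) {
  stopifnot(inherits(probe, "probe_model"))
  if (!protocol$analyte %in% c("DA", "5HT", "pH"))
    stop("unknown analyte: ", protocol$analyte, call. = FALSE)
  levels <- seq(protocol$min, protocol$max, by = protocol$step)
  dwell <- protocol$dwell
  lev_seq <- rep(rep(levels, each = dwell), times = protocol$replicates)
  n <- length(lev_seq)
  idx_in_level <- rep(rep(seq_len(dwell), times = length(levels)),
                      times = protocol$replicates)
  quarter <- dwell_quarter(idx_in_level, dwell)
  t <- (seq_len(n) - 1) * probe$waveform$repetition_period
  da <- ht <- rep(0, n); ph <- rep(7.4, n)
  if (protocol$analyte == "DA") da <- lev_seq
  if (protocol$analyte == "5HT") ht <- lev_seq
  if (protocol$analyte == "pH") ph <- lev_seq
  cur <- with_seed(seed, synthesize_sweep_matrix(probe, da, ht, ph, t))
  structure(list(
    current = cur,
    labels = data.frame(DA = da, `5HT` = ht, pH = ph, check.names = FALSE),
    time = t, quarter = quarter, level = lev_seq,
    analyte = protocol$analyte, probe_id = probe$probe_id,
    waveform = probe$waveform
  ), class = "invitro_dataset")
}

#' Generate the standard three-protocol dataset bundle for one probe
#'
#' @param probe A [sample_probe_model()] result.
#' @param seed Base seed; each protocol gets a derived stage seed.
#' @param protocols Named list of protocols for `DA`, `5HT` and `pH`;
#'   defaults to [invitro_protocol()] for each.
#' @return Named list of three `invitro_dataset`s.
#' @export
generate_probe_datasets <- function(probe, seed = 1, protocols = NULL) {
  protocols <- protocols %||% list(DA = invitro_protocol("DA"),
                                   `5HT` = invitro_protocol("5HT"),
                                   pH = invitro_protocol("pH"))
  out <- lapply(names(protocols), function(a)
    generate_invitro_dataset(probe, protocols[[a]],
                             seed = derive_seed(seed, paste0("invitro-", a))))
  names(out) <- names(protocols)
  out
}

#' Read/write a sweep container
#'
#' Plain-text container for sweep matrices: one row per sweep, with
#' metadata columns (`time`, `quarter`, `DA`, `5HT`, `pH`) followed by the
#' current samples (`s1` ... `sN`). Waveform constants and the probe id
#' travel in a JSON-like header comment line. Intended for small fixtures
#' and for round-tripping decoded sessions; large runs stay in memory.
#'
#' @param x An `invitro_dataset` (or compatible list) to write.
#' @param path File path (CSV).
#' @return `read_sweep_container()` returns an `invitro_dataset`-shaped
#'   list; `write_sweep_container()` returns `path` invisibly.
#' @export
write_sweep_container <- function(x, path) {
  hdr <- sprintf("# voltdecode sweep container; probe_id=%s; analyte=%s; sweep_samples=%d; repetition_period=%.10g",
                 x$probe_id, x$analyte %||% "NA",
                 ncol(x$current), x$waveform$repetition_period)
  df <- data.frame(time = x$time, quarter = x$quarter,
                   DA = x$labels$DA, `5HT` = x$labels$`5HT`,
                   pH = x$labels$pH, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$current))
  names(df)[-(1:5)] <- paste0("s", seq_len(ncol(x$current)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_container
#' @param waveform Waveform spec to attach on read (the container stores
#'   only derived constants).
#' @export
read_sweep_container <- function(path, waveform = waveform_spec()) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "# voltdecode sweep container"))
    stop("not a voltdecode sweep container: ", path, call. = FALSE)
  meta <- strsplit(sub("^# voltdecode sweep container; ", "", hdr), "; ")[[1]]
  kv <- do.call(rbind, strsplit(meta, "="))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  need <- c("time", "quarter", "DA", "5HT", "pH")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("container missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  scols <- grep("^s[0-9]+$", names(df))
  cur <- as.matrix(df[, scols, drop = FALSE])
  dimnames(cur) <- NULL
  if (ncol(cur) != as.integer(meta[["sweep_samples"]]))
    stop("sweep length mismatch with container header", call. = FALSE)
  structure(list(
    current = cur,
    labels = df[, c("DA", "5HT", "pH")],
    time = df$time, quarter = as.integer(df$quarter),
    level = NULL,
    analyte = if (meta[["analyte"]] == "NA") NULL else meta[["analyte"]],
    probe_id = meta[["probe_id"]],
    waveform = waveform
  ), class = "invitro_dataset")
}
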