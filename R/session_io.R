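#' Electrode region labels
#' @export
REGION_LABELS <- c("CA1_PYR", "CA1_SR", "CA3", "DG", "CORPUS_CALLOSUM", "OUT")

#' Electrode site descriptor
#'
#' @param site_id unique site identifier
#' @param shank_index,depth_index probe geometry indices
#' @param region_label one of [REGION_LABELS]
#' @param usable logical, site usable for analysis
#' @return one-row data.frame
#' @export
electrode_site <- function(site_id, shank_index = 1L, depth_index = 1L,
                           region_label = "CA1_PYR", usable = TRUE) {
  if (!region_label %in% REGION_LABELS)
    stop("electrode_site: unknown region label: ", region_label)
  data.frame(site_id = site_id, shank_index = as.integer(shank_index),
             depth_index = as.integer(depth_index),
             region_label = region_label, usable = usable,
             stringsAsFactors = FALSE)
}

#' In-memory LFP recording session
#'
#' One 60-minute home-cage recording: multi-site LFP (uV, >= 1 kHz after
#' downsampling), a 30 Hz position track, and per-site region labels.
#'
#' @param mouse_id mouse identifier
#' @param genotype `"E3"` or `"E4"` (human APOE knock-in line)
#' @param age_group `"YOUNG"`, `"MIDDLE"` or `"OLD"`
#' @param session_index session number (1-5)
#' @param sample_rate LFP sampling rate (Hz, >= 1000)
#' @param signals site x time numeric matrix (uV); row i belongs to
#'   `sites[i, ]`
#' @param sites data.frame of [electrode_site()] rows
#' @param position data.frame `t_s`, `x_cm`, `y_cm` at 30 Hz
#' @return object of class `lfp_session`
#' @export
lfp_session <- function(mouse_id, genotype = c("E3", "E4"),
                        age_group = c("OLD", "MIDDLE", "YOUNG"),
                        session_index = 1L, sample_rate, signals, sites,
                        position) {
  genotype <- match.arg(genotype)
  age_group <- match.arg(age_group)
  s <- structure(list(mouse_id = mouse_id, genotype = genotype,
                      age_group = age_group,
                      session_index = as.integer(session_index),
                      sample_rate = sample_rate, signals = signals,
                      sites = sites, position = position),
                 class = "lfp_session")
  viol <- validate_session(s)
  if (length(viol)) stop("lfp_session: ", paste(viol, collapse = "; "))
  s
}

#' Validate an LFP session
#'
#' Pure check of the session invariants. Returns a character vector of
#' violations (empty when valid); it reports rather than throws.
#'
#' @param session an `lfp_session` (or structurally similar list)
#' @return character vector of violation messages
#' @export
validate_session <- function(session) {
  v <- character(0)
  if (!is.matrix(session$signals))
    v <- c(v, "signals must be a site x time matrix")
  else if (nrow(session$signals) != nrow(session$sites))
    v <- c(v, "number of signal rows differs from number of sites")
  if (session$sample_rate < 1000)
    v <- c(v, sprintf("sample_rate %g < 1000 Hz", session$sample_rate))
  if (anyDuplicated(session$sites$site_id))
    v <- c(v, "duplicate site_id within session")
  if (!all(session$sites$region_label %in% REGION_LABELS))
    v <- c(v, "unknown region label")
  pos <- session$position
  if (is.null(pos) || nrow(pos) < 2) {
    v <- c(v, "position track missing or too short")
  } else {
    if (any(diff(pos$t_s) <= 0))
      v <- c(v, "position timestamps not strictly increasing")
    if (is.matrix(session$signals)) {
      dur <- ncol(session$signals) / session$sample_rate
      if (pos$t_s[1] > 1 || pos$t_s[nrow(pos)] < dur - 1)
        v <- c(v, sprintf(
          "position track [%.2f, %.2f] s does not cover signal duration %.2f s within 1 s",
          pos$t_s[1], pos$t_s[nrow(pos)], dur))
    }
  }
  v
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf("<lfp_session> mouse %s (%s, %s) session %d: %d site(s), %.1f s @ %g Hz\n",
              x$mouse_id, x$genotype, x$age_group, x$session_index,
              nrow(x$sites), ncol(x$signals) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Write a session bundle to disk
#'
#' Bundle layout: `signals.f32` (raw little-endian float32, the site x
#' time matrix in column-major order), `meta.json` (sample rate, site
#' table, mouse metadata, array dimensions), `position.csv`
#' (`t_s,x_cm,y_cm`). The format is language-neutral: any environment that
#' can read raw float32 and JSON can load a bundle.
#'
#' @param session an `lfp_session`
#' @param path bundle directory to create
#' @param overwrite overwrite an existing bundle, default `FALSE`
#' @return invisible `path`
#' @export
write_session_bundle <- function(session, path, overwrite = FALSE) {
  viol <- validate_session(session)
  if (length(viol)) stop("write_session_bundle: ", paste(viol, collapse = "; "))
  if (dir.exists(path) && length(dir(path)) && !overwrite)
    stop("write_session_bundle: '", path, "' exists; set overwrite = TRUE")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = 1L,
               mouse_id = session$mouse_id, genotype = session$genotype,
               age_group = session$age_group,
               session_index = session$session_index,
               sample_rate = session$sample_rate,
               n_sites = nrow(session$signals),
               n_samples = ncol(session$signals),
               dtype = "float32_le_col_major",
               sites = session$sites)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "signals.f32"), "wb")
  on.exit(close(con))
  writeBin(as.vector(session$signals), con, size = 4L, endian = "little")
  utils::write.csv(session$position, file.path(path, "position.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' @param path bundle directory written by [write_session_bundle()]
#' @return a validated `lfp_session`
#' @export
read_session_bundle <- function(path) {
  mj <- file.path(path, "meta.json")
  if (!file.exists(mj))
    stop("read_session_bundle: missing meta.json sidecar in '", path, "'")
  meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  if (meta$sample_rate < 1000)
    stop("read_session_bundle: sample_rate below 1000 Hz")
  if (!all(meta$sites$region_label %in% REGION_LABELS))
    stop("read_session_bundle: unknown region label in site table")
  n <- meta$n_sites * meta$n_samples
  con <- file(file.path(path, "signals.f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(x) != n) stop("read_session_bundle: truncated signals.f32")
  pos <- utils::read.csv(file.path(path, "position.csv"))
  lfp_session(mouse_id = meta$mouse_id, genotype = meta$genotype,
              age_group = meta$age_group, session_index = meta$session_index,
              sample_rate = as.numeric(meta$sample_rate),
              signals = matrix(x, nrow = meta$n_sites),
              sites = as.data.frame(meta$sites), position = pos)
}

#' Converter stub for the public hc-26 LFP repository
#'
#' The study's recordings are deposited as 0-300 Hz filtered LFP, MUA
#' spike times, position tracking and metadata. Converting that deposit
#' into session bundles requires its MATLAB-side container files, which
#' this package does not ship a reader for; this stub documents the
#' mapping (LFP array -> `signals.f32`; tracking -> `position.csv`;
#' electrode metadata -> `meta.json` site table) and fails informatively.
#'
#' @param path path to a downloaded hc-26 session
#' @export
read_crcns_hc26 <- function(path) {
  stop("read_crcns_hc26: converter stub; convert the deposit to the ",
       "documented bundle layout (signals.f32 + meta.json + position.csv) ",
       "and use read_session_bundle()")
}
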