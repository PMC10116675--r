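# Tensor encoding of read windows: one (d_window x d_reads x 7) track per
# sample track, depth-concatenated into a composite sample.

#' Encoding configuration
#'
#' Geometry and normalisation of the pileup tensor encoding. Each track is
#' encoded as a `(d_window, d_reads, 7)` array whose channels are, in order:
#' one-hot A, C, G, T, base quality, mapping quality, reverse-strand flag.
#' Phred qualities are divided by fixed divisors and clipped to \[0, 1\].
#'
#' @param d_window odd window length in bases (default 101)
#' @param d_reads maximum reads per track (default 200)
#' @param n_context number of context tracks (default 3, giving 5 tracks
#'   total together with germline and tumour)
#' @param qual_norm_base divisor mapping base phred scores into \[0, 1\]
#' @param qual_norm_map divisor mapping mapping-quality scores into \[0, 1\]
#' @return object of class `encoding_config`
#' @export
encoding_config <- function(d_window = 101L, d_reads = 200L, n_context = 3L,
                            qual_norm_base = 42, qual_norm_map = 60) {
  d_window <- as.integer(d_window)
  d_reads <- as.integer(d_reads)
  n_context <- as.integer(n_context)
  if (d_window < 1L || d_window %% 2L == 0L)
    stop_usage("d_window must be odd and >= 1")
  if (d_reads < 1L) stop_usage("d_reads must be >= 1")
  if (n_context < 0L) stop_usage("n_context must be >= 0")
  if (qual_norm_base <= 0 || qual_norm_map <= 0)
    stop_usage("quality divisors must be positive")
  structure(list(d_window = d_window, d_reads = d_reads,
                 n_context = n_context, qual_norm_base = qual_norm_base,
                 qual_norm_map = qual_norm_map),
            class = "encoding_config")
}

#' Encode one track's read window as a tensor
#'
#' Fills a `(d_window, d_reads, 7)` array: row `r`, window position `w`
#' carries the one-hot base identity, normalised base quality, normalised
#' mapping quality and strand flag of read `r`'s base aligned to reference
#' position `pos - (d_window-1)/2 + w - 1`. Cells not covered by a read
#' (including read-internal deletion gaps) and rows beyond the pileup depth
#' stay exactly zero. 'N' bases get an all-zero one-hot but their qualities
#' are still written.
#'
#' @param reads list of [aligned_read()] from [extract_window()]
#' @param site the [candidate_site()] at the window centre
#' @param config an [encoding_config()]
#' @return numeric array `(d_window, d_reads, 7)`
#' @export
encode_track <- function(reads, site, config = encoding_config()) {
  a <- array(0, c(config$d_window, config$d_reads, 7L))
  wb <- window_bounds(site, config)
  n <- min(length(reads), config$d_reads)
  for (r in seq_len(n)) {
    rd <- reads[[r]]
    inwin <- rd$ref_pos >= wb$start0 & rd$ref_pos < wb$end0
    if (!any(inwin)) next
    w <- rd$ref_pos[inwin] - wb$start0 + 1L
    b <- rd$bases[inwin]
    q <- rd$quals[inwin]
    ch <- match(b, BASES)           # NA for 'N' and other ambiguity codes
    hit <- !is.na(ch)
    if (any(hit)) a[cbind(w[hit], r, ch[hit])] <- 1
    a[cbind(w, r, 5L)] <- pmin(1, pmax(0, q / config$qual_norm_base))
    a[cbind(w, r, 6L)] <- pmin(1, pmax(0, rd$mapq / config$qual_norm_map))
    a[cbind(w, r, 7L)] <- as.numeric(rd$is_reverse)
  }
  a
}

#' Assemble a composite sample from per-track tensors
#'
#' Depth-concatenates the track tensors in the fixed order germline, tumour,
#' context_1..context_n, yielding an array of shape
#' `(d_window, d_reads, 7 * (2 + n_context))`.
#'
#' @param germline,tumour `(d_window, d_reads, 7)` arrays from
#'   [encode_track()]
#' @param contexts list of context-track tensors (length `n_context`)
#' @param site the encoded [candidate_site()]
#' @param config an [encoding_config()]
#' @param label optional "mutation"/"artefact" label
#' @return object of class `composite_sample` with fields `values`, `site`,
#'   `label`, `tracks`
#' @export
assemble_composite <- function(germline, tumour, contexts = list(),
                               site = NULL, config = encoding_config(),
                               label = NA_character_) {
  want <- c(config$d_window, config$d_reads, 7L)
  check_shape <- function(x, name) {
    if (!is.array(x) || length(dim(x)) != 3 || !all(dim(x) == want))
      stop_data("track '", name, "' has shape (",
                paste(dim(x), collapse = ","), "), expected (",
                paste(want, collapse = ","), ")")
  }
  check_shape(germline, "germline")
  check_shape(tumour, "tumour")
  if (length(contexts) != config$n_context)
    stop_data("expected ", config$n_context, " context track(s), got ",
              length(contexts))
  for (i in seq_along(contexts))
    check_shape(contexts[[i]], paste0("context_", i))
  tracks <- c("germline", "tumour",
              if (config$n_context > 0) paste0("context_", seq_len(config$n_context)))
  values <- array(c(germline, tumour, unlist(contexts, use.names = FALSE)),
                  dim = c(config$d_window, config$d_reads, 7L * length(tracks)))
  if (is.na(label) && !is.null(site) && !is.null(site$label)) label <- site$label
  structure(list(values = values, site = site, label = label,
                 tracks = tracks, config = config),
            class = "composite_sample")
}

#' @export
print.composite_sample <- function(x, ...) {
  cat(sprintf("<composite_sample> (%s) tracks=%s label=%s\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$tracks, collapse = ","), x$label))
  invisible(x)
}

#' Extract one track's tensor from a composite sample
#'
#' @param sample a `composite_sample`
#' @param track track index (1-based) or name
#' @return `(d_window, d_reads, 7)` array
#' @export
track_block <- function(sample, track) {
  if (is.character(track)) track <- match(track, sample$tracks)
  if (is.na(track) || track < 1 || track > length(sample$tracks))
    stop_usage("unknown track")
  sample$values[, , (7L * (track - 1L) + 1L):(7L * track), drop = FALSE]
}

#' Drop the context tracks from a composite sample
#'
#' Keeps only the germline and tumour depth blocks, producing the
#' context-free representation used to quantify what the context tracks
#' contribute.
#'
#' @param sample a `composite_sample`
#' @return a `composite_sample` with 2 tracks (depth 14)
#' @export
strip_context <- function(sample) {
  sample$values <- sample$values[, , 1:14, drop = FALSE]
  sample$tracks <- sample$tracks[1:2]
  sample$config$n_context <- 0L
  sample
}

#' Scramble base identities of a composite sample
#'
#' Draws uniformly one of four substitutions — identity, A<->T, C<->G, or
#' both — and applies the corresponding permutation of the one-hot channel
#' slices identically across all tracks. Swaps stay within purines and
#' pyrimidines so transition/transversion information is preserved. The same
#' substitution is applied to the site's ref/alt metadata. Quality and
#' strand channels are untouched.
#'
#' @param sample a `composite_sample`
#' @param rng_seed optional seed for the substitution draw
#' @param swap force a particular substitution: one of "none", "AT", "CG",
#'   "both" (bypasses the random draw)
#' @return the scrambled `composite_sample`; the chosen substitution is
#'   recorded in attribute `"swap"`
#' @export
scramble_bases <- function(sample, rng_seed = NULL, swap = NULL) {
  choices <- c("none", "AT", "CG", "both")
  if (is.null(swap)) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    swap <- sample(choices, 1)
  }
  swap <- match.arg(swap, choices)
  n_tracks <- length(sample$tracks)
  perm <- switch(swap,
                 none = 1:4,
                 AT = c(4L, 2L, 3L, 1L),
                 CG = c(1L, 3L, 2L, 4L),
                 both = c(4L, 3L, 2L, 1L))
  if (swap != "none") {
    for (t in seq_len(n_tracks)) {
      off <- 7L * (t - 1L)
      sample$values[, , off + 1:4] <- sample$values[, , off + perm]
    }
    map <- switch(swap, AT = c(A = "T", C = "C", G = "G", T = "A"),
                  CG = c(A = "A", C = "G", G = "C", T = "T"),
                  both = c(A = "T", C = "G", G = "C", T = "A"))
    if (!is.null(sample$site)) {
      sample$site$ref_base <- unname(map[sample$site$ref_base])
      sample$site$alt_base <- unname(map[sample$site$alt_base])
    }
  }
  attr(sample, "swap") <- swap
  sample
}

#' Save composite samples to a flat binary container
#'
#' Writes the stacked tensor values as little-endian float32 with a JSON
#' sidecar recording shapes, track identities, per-sample site metadata and
#' the encoding configuration.
#'
#' @param samples list of `composite_sample` (homogeneous shapes)
#' @param prefix output path prefix; writes `<prefix>.bin` and
#'   `<prefix>.json`
#' @param seed optional seed to record in the sidecar
#' @return invisibly, the two file paths
#' @export
save_tensors <- function(samples, prefix, seed = NULL) {
  stopifnot(length(samples) > 0)
  dims <- dim(samples[[1]]$values)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (s in samples) {
    stopifnot(all(dim(s$values) == dims))
    writeBin(as.numeric(s$values), con, size = 4, endian = "little")
  }
  meta <- list(
    n = length(samples), shape = dims,
    tracks = samples[[1]]$tracks,
    config = unclass(samples[[1]]$config),
    seed = seed,
    sites = lapply(samples, function(s) {
      c(unclass(s$site)[c("chrom", "pos", "ref_base", "alt_base",
                          "mutation_class", "vaf")],
        list(label = s$label))
    }))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             paste0(prefix, ".json"))
  invisible(c(paste0(prefix, ".bin"), paste0(prefix, ".json")))
}

#' Load composite samples saved by [save_tensors()]
#'
#' @param prefix path prefix used at save time
#' @return list of `composite_sample`
#' @export
load_tensors <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"), simplifyVector = FALSE)
  dims <- as.integer(unlist(meta$shape))
  per <- prod(dims)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  cfg <- do.call(encoding_config, meta$config)
  lapply(seq_len(meta$n), function(i) {
    v <- readBin(con, numeric(), n = per, size = 4, endian = "little")
    si <- meta$sites[[i]]
    site <- candidate_site(si$chrom, si$pos, si$ref_base, si$alt_base,
                           mutation_class = si$mutation_class %||% NA_character_,
                           vaf = si$vaf %||% NA_real_,
                           label = si$label %||% NA_character_)
    structure(list(values = array(v, dims), site = site,
                   label = si$label %||% NA_character_,
                   tracks = unlist(meta$tracks), config = cfg),
              class = "composite_sample")
  })
}
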