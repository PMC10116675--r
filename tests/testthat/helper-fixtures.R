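# shared fixtures and independent oracles

mk_read <- function(qname, start, bases, quals = NULL, mapq = 60L,
                    rev = FALSE, chrom = "c1", cigar = NULL) {
  if (length(bases) == 1 && nchar(bases) > 1) bases <- strsplit(bases, "")[[1]]
  if (is.null(quals)) quals <- rep(30L, length(bases))
  aligned_read(qname, chrom, start, bases, quals, mapq, rev, cigar)
}

mk_site <- function(pos = 1000L, ref = "A", alt = "C", chrom = "c1", ...) {
  candidate_site(chrom, pos, ref, alt, ...)
}

# random read fixture around a site; includes reverse reads, variable
# lengths, occasional N bases and occasional deletion-containing CIGARs
random_reads <- function(n, site, enc, seed) {
  set.seed(seed)
  half <- (enc$d_window - 1L) %/% 2L
  pos0 <- site$pos - 1L
  lapply(seq_len(n), function(i) {
    L <- sample(6:40, 1)
    start <- pos0 - half - L + sample.int(enc$d_window + 2L * L, 1) - 1L
    bases <- sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                    prob = c(.24, .24, .24, .24, .04))
    quals <- sample(2:41, L, replace = TRUE)
    cigar <- NULL
    if (runif(1) < 0.3 && L > 6) {
      k <- sample(2:(L - 2), 1)  # deletion after k query bases
      cigar <- sprintf("%dM%dD%dM", k, sample(1:3, 1), L - k)
    }
    mk_read(sprintf("r%03d", i), start, bases, quals,
            mapq = sample(0:60, 1), rev = runif(1) < 0.5,
            chrom = site$chrom, cigar = cigar)
  })
}

# independent per-cell encoding oracle: straightforward loops over each
# read's aligned bases, no shared code with encode_track's vectorised path
naive_encode <- function(reads, site, enc) {
  half <- (enc$d_window - 1L) %/% 2L
  lo <- site$pos - 1L - half
  a <- array(0, c(enc$d_window, enc$d_reads, 7L))
  base_ch <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (r in seq_len(min(length(reads), enc$d_reads))) {
    rd <- reads[[r]]
    for (k in seq_along(rd$ref_pos)) {
      w <- rd$ref_pos[k] - lo + 1L
      if (w >= 1L && w <= enc$d_window) {
        ch <- base_ch[rd$bases[k]]
        if (!is.na(ch)) a[w, r, ch] <- 1
        a[w, r, 5L] <- min(1, max(0, rd$quals[k] / enc$qual_norm_base))
        a[w, r, 6L] <- min(1, max(0, rd$mapq / enc$qual_norm_map))
        a[w, r, 7L] <- as.numeric(rd$is_reverse)
      }
    }
  }
  a
}

# small composite sample with white-noise values, for network plumbing tests
noise_sample <- function(shape, label = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(values = array(rnorm(prod(shape), 0, 0.3), shape),
                 site = NULL, label = label, tracks = "synthetic"),
            class = "composite_sample")
}

# linearly separable toy set: class shifts the mean of a fixed value block
separable_set <- function(n, shape, shift = 0.8, seed = 1) {
  set.seed(seed)
  y <- rep(c("mutation", "artefact"), length.out = n)
  lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(shape), 0, 0.3), shape)
    if (y[i] == "mutation") v[, , 1] <- v[, , 1] + shift
    structure(list(values = v, site = NULL, label = y[i],
                   tracks = "synthetic"),
              class = "composite_sample")
  })
}

# desk-scale study conditions shared by the heavier statistical tests:
# the smallest geometry the three-stage pooling admits, with coverage and
# read length scaled so pileups stay information-dense
study_encoding <- function(n_context = 3L) {
  encoding_config(d_window = 27L, d_reads = 27L, n_context = n_context)
}

study_sim_config <- function(...) {
  sim_config(coverage_mean = 40, read_length = 50, vaf = 0.5, ...)
}
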