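# window extraction, tensor encoding, composite assembly, base scrambling,
# candidate filtering

test_that("extract_window returns overlapping reads, ordered and truncated", {
  enc <- encoding_config(d_window = 101, d_reads = 200)
  site <- mk_site(pos = 1000)

  # no reads in the region -> empty list, not an error
  far <- read_set(list(mk_read("r1", 5000L, "ACGT")))
  expect_identical(extract_window(far, site, enc), list())

  # 250 overlapping reads -> first 200 kept
  many <- read_set(lapply(1:250, function(i)
    mk_read(sprintf("q%03d", i), 960L + (i %% 50L), strrep("A", 30))))
  got <- extract_window(many, site, enc)
  expect_length(got, 200)

  # pileup-sort contract: alt-supporting reads first, then other
  # mismatches, then reference reads, then non-covering reads; within a
  # group ascending start with stable name tie-break
  site2 <- mk_site(pos = 1000, ref = "A", alt = "C")
  grp_reads <- list(mk_read("nref1", 995L, strrep("A", 12)),
                    mk_read("nalt1", 996L, strrep("C", 12)),
                    mk_read("nother", 997L, strrep("G", 12)),
                    mk_read("nfar", 955L, strrep("A", 20)),  # misses locus
                    mk_read("nalt0", 996L, strrep("C", 12)),
                    mk_read("nref0", 990L, strrep("A", 15)))
  ord <- vapply(extract_window(read_set(grp_reads), site2, enc), `[[`,
                character(1), "qname")
  expect_equal(ord, c("nalt0", "nalt1", "nother", "nref0", "nref1", "nfar"))

  # brute-force interval-overlap oracle on a random fixture, including the
  # boundary case of a read ending exactly one base before the window
  reads <- random_reads(80, site, enc, seed = 42)
  reads <- c(reads, list(mk_read("edge", 1000L - 51L - 10L, strrep("C", 10))))
  rs <- read_set(reads)
  got <- extract_window(rs, site, enc)
  lo <- 1000L - 51L  # 0-based window start
  hi <- lo + 101L    # half-open end
  want <- vapply(reads, function(r) r$span[1] < hi && r$span[2] > lo,
                 logical(1))
  expect_setequal(vapply(got, `[[`, character(1), "qname"),
                  vapply(reads[want], `[[`, character(1), "qname"))
  expect_false("edge" %in% vapply(got, `[[`, character(1), "qname"))
})

test_that("extract_window rejects unknown chromosomes", {
  rs <- read_set(list(mk_read("r1", 10L, "ACGT", chrom = "chr1")))
  expect_error(extract_window(rs, mk_site(chrom = "chrX"), encoding_config()),
               "chrX")
})

test_that("encode_track matches direct construction on canonical cases", {
  enc <- encoding_config(d_window = 101, d_reads = 200,
                         qual_norm_base = 42, qual_norm_map = 60)
  site <- mk_site(pos = 1000, ref = "A", alt = "G")

  # empty pileup -> all-zero tensor of the declared shape
  z <- encode_track(list(), site, enc)
  expect_identical(dim(z), c(101L, 200L, 7L))
  expect_true(all(z == 0))

  # one forward read spanning the window, all 'A', qualities at the divisors
  rd <- mk_read("r1", 1000L - 51L - 10L, strrep("A", 121),
                quals = rep(42L, 121), mapq = 60L, rev = FALSE)
  a <- encode_track(list(rd), site, enc)
  expect_true(all(a[, 1, 1] == 1))           # A channel on at all positions
  expect_true(all(a[, 1, 2:4] == 0))
  expect_true(all(a[, 1, 5] == 1))           # base qual / 42
  expect_true(all(a[, 1, 6] == 1))           # map qual / 60
  expect_true(all(a[, 1, 7] == 0))
  expect_true(all(a[, 2:200, ] == 0))

  # one reverse read covering only the centre base 'G'
  rd2 <- mk_read("r2", 999L, "G", quals = 21L, mapq = 30L, rev = TRUE)
  b <- encode_track(list(rd2), site, enc)
  expect_equal(b[51, 1, ], c(0, 0, 1, 0, 0.5, 0.5, 1))
  b[51, 1, ] <- 0
  expect_true(all(b == 0))
})

test_that("encoding agrees with a naive per-cell oracle on random fixtures", {
  enc <- encoding_config(d_window = 21, d_reads = 30)
  site <- mk_site(pos = 500)
  for (seed in 1:20) {
    reads <- random_reads(sample(0:40, 1), site, enc, seed = seed)
    win <- extract_window(read_set(reads), site, enc)
    got <- encode_track(win, site, enc)
    expect_identical(dim(got), c(21L, 30L, 7L))
    expect_equal(got, naive_encode(win, site, enc))
    onehot <- apply(got[, , 1:4], c(1, 2), sum)
    expect_true(all(onehot %in% c(0, 1)))
  }
})

test_that("the candidate locus maps to the central window index", {
  enc <- encoding_config(d_window = 101, d_reads = 10)
  site <- mk_site(pos = 777, ref = "T", alt = "C")
  rd <- mk_read("r", 776L, "T", quals = 40L)   # covers exactly the locus
  a <- encode_track(list(rd), site, enc)
  expect_equal(which(a[, 1, 4] == 1), 51)      # (d_window - 1)/2 + 1
})

test_that("deletions leave zero gaps and insertions add no column", {
  enc <- encoding_config(d_window = 21, d_reads = 5)
  site <- mk_site(pos = 100)
  # 4M 3D 4M: bases 5..8 align after a 3-base reference gap
  rd <- mk_read("del", 95L, "AAAACCCC", quals = rep(30L, 8),
                cigar = "4M3D4M")
  a <- encode_track(list(rd), site, enc)
  covered <- which(apply(a[, 1, , drop = FALSE] != 0, 1, any))
  lo <- 100L - 1L - 10L
  expect_equal(covered, c(95:98, 102:105) - lo + 1L)
  # 4M2I4M consumes 10 query bases but only 8 reference positions
  rd2 <- mk_read("ins", 95L, "AAAATTCCCC", quals = rep(30L, 10),
                 cigar = "4M2I4M")
  b <- encode_track(list(rd2), site, enc)
  covered2 <- which(apply(b[, 1, , drop = FALSE] != 0, 1, any))
  expect_equal(covered2, c(95:102) - lo + 1L)
  expect_equal(b[(99:102) - lo + 1L, 1, 2], rep(1, 4))  # C after the insertion
})

test_that("N bases zero the one-hot but keep the quality channels", {
  enc <- encoding_config(d_window = 21, d_reads = 5)
  site <- mk_site(pos = 100)
  rd <- mk_read("n", 99L, "N", quals = 21L, mapq = 30L)
  a <- encode_track(list(rd), site, enc)
  expect_true(all(a[11, 1, 1:4] == 0))
  expect_equal(a[11, 1, 5], 0.5)
  expect_equal(a[11, 1, 6], 0.5)
})

test_that("assemble_composite concatenates tracks in order and checks shapes", {
  enc <- encoding_config(d_window = 21, d_reads = 10, n_context = 3)
  t0 <- array(0, c(21, 10, 7))
  mk <- function(v) { a <- t0; a[1, 1, 1] <- v; a }
  s <- assemble_composite(mk(1), mk(2), list(mk(3), mk(4), mk(5)),
                          site = mk_site(), config = enc)
  expect_identical(dim(s$values), c(21L, 10L, 35L))
  expect_equal(s$tracks, c("germline", "tumour", paste0("context_", 1:3)))
  for (i in 1:5) expect_equal(track_block(s, i)[1, 1, 1], i)

  # context-free assembly
  enc0 <- encoding_config(d_window = 21, d_reads = 10, n_context = 0)
  s0 <- assemble_composite(mk(1), mk(2), list(), config = enc0)
  expect_identical(dim(s0$values), c(21L, 10L, 14L))

  # wrong shapes and counts are reported with the offending track
  bad <- array(0, c(21, 5, 7))
  expect_error(assemble_composite(mk(1), mk(2), list(mk(3), bad, mk(5)),
                                  config = enc), "context_2")
  expect_error(assemble_composite(mk(1), mk(2), list(mk(3)), config = enc),
               "3 context")
})

test_that("scramble_bases permutes one-hot slices consistently", {
  enc <- encoding_config(d_window = 21, d_reads = 10, n_context = 1)
  site <- mk_site(pos = 100, ref = "A", alt = "G")
  reads <- random_reads(15, site, enc, seed = 7)
  tr <- encode_track(extract_window(read_set(reads), site, enc), site, enc)
  s <- assemble_composite(tr, tr, list(tr), site = site, config = enc)

  # A<->T on one-hot (1,0,0,0) -> (0,0,0,1), in every track block
  sw <- scramble_bases(s, swap = "AT")
  for (t in 1:3) {
    off <- 7 * (t - 1)
    expect_equal(sw$values[, , off + 1], s$values[, , off + 4])
    expect_equal(sw$values[, , off + 4], s$values[, , off + 1])
    expect_equal(sw$values[, , off + 2:3], s$values[, , off + 2:3])
    expect_equal(sw$values[, , off + 5:7], s$values[, , off + 5:7])
  }
  expect_equal(sw$site$ref_base, "T")
  expect_equal(sw$site$alt_base, "G")

  # double swaps are involutions
  for (swap in c("AT", "CG", "both")) {
    twice <- scramble_bases(scramble_bases(s, swap = swap), swap = swap)
    expect_equal(twice$values, s$values)
    expect_equal(twice$site$ref_base, s$site$ref_base)
  }

  # scramble(encode(reads)) == encode(reads with substituted letters),
  # where the site's ref/alt metadata is substituted alongside the reads
  subst <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  reads2 <- lapply(reads, function(r) { r$bases <- unname(subst[r$bases]); r })
  site2 <- mk_site(pos = 100, ref = unname(subst["A"]),
                   alt = unname(subst["G"]))
  tr2 <- encode_track(extract_window(read_set(reads2), site2, enc),
                      site2, enc)
  sboth <- scramble_bases(s, swap = "both")
  expect_equal(track_block(sboth, 1)[, , 1:4], tr2[, , 1:4])

  # the draw itself is seeded and uniform over the four substitutions
  draws <- vapply(1:40, function(i)
    attr(scramble_bases(s, rng_seed = i), "swap"), character(1))
  expect_identical(draws, vapply(1:40, function(i)
    attr(scramble_bases(s, rng_seed = i), "swap"), character(1)))
  expect_true(all(c("none", "AT", "CG", "both") %in% draws))
})

test_that("filter_candidates applies the whitelist, preserving order", {
  sites <- list(mk_site(pos = 1, mutation_class = "exonic"),
                mk_site(pos = 2, mutation_class = "intronic"),
                mk_site(pos = 3, mutation_class = "UTR5;UTR3"),
                mk_site(pos = 4, mutation_class = NA),
                mk_site(pos = 5, mutation_class = "upstream"))
  kept <- filter_candidates(sites)
  expect_equal(vapply(kept, `[[`, integer(1), "pos"), c(1L, 3L, 5L))
  expect_length(default_mutation_classes(), 9)
  # empty whitelist disables filtering
  expect_length(filter_candidates(sites, character(0)), 5)
  expect_identical(filter_candidates(list()), list())
})

test_that("tensor round-trip through the binary container preserves values", {
  enc <- encoding_config(d_window = 21, d_reads = 10, n_context = 0)
  site <- mk_site(pos = 100, ref = "A", alt = "C")
  reads <- random_reads(10, site, enc, seed = 3)
  tr <- encode_track(extract_window(read_set(reads), site, enc), site, enc)
  s <- assemble_composite(tr, tr, list(), site = site, config = enc,
                          label = "mutation")
  prefix <- file.path(tempdir(), "tens")
  save_tensors(list(s, s), prefix, seed = 11)
  back <- load_tensors(prefix)
  expect_length(back, 2)
  expect_equal(back[[1]]$values, s$values, tolerance = 1e-6)
  expect_equal(back[[1]]$label, "mutation")
  expect_equal(back[[2]]$site$pos, 100L)
})
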