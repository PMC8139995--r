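# Consensus module: DUST masking, type classification, normalization,
# the filter cascade, callset intersection and the three-way comparison.

test_that("homopolymers mask completely, random sequence does not", {
  m <- dust_mask(strrep("A", 100))
  expect_identical(m, data.frame(start = 1L, end = 100L))
  expect_identical(nrow(dust_mask("AC")), 0L)
  set.seed(1)
  r <- rand_seq(100)
  # a typical random string scores far below threshold everywhere
  expect_identical(nrow(dust_mask(r)), nrow(dust_oracle(r)))
})

test_that("short-period repeats are masked, like the reference masker", {
  # (ACGT)n uses only 4 of 64 triplet types, so its triplet score grows
  # linearly and crosses the threshold, exactly as dustmasker masks it
  m <- dust_mask(strrep("ACGT", 25))
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 1L)
  expect_identical(m$end, 100L)
  expect_gt(nrow(dust_mask(strrep("AT", 50))), 0L)
})

test_that("dust_mask equals the brute-force triplet-score oracle", {
  set.seed(42)
  for (k in 1:30) {
    # mix plain random strings with low-complexity injections
    s <- rand_seq(100)
    if (k %% 3 == 0) {
      at <- sample(60, 1)
      substr(s, at, at + 19) <- strrep(sample(c("A", "T", "AC", "AG"), 1), 20)
    }
    expect_identical(dust_mask(s), dust_oracle(s), label = s)
  }
})

test_that("N breaks triplets and prevents masking across it", {
  s <- paste0(strrep("A", 30), "N", strrep("A", 30))
  m <- dust_mask(s)
  expect_gt(nrow(m), 0)
  # the poly-A runs are masked on both sides
  expect_true(any(m$start <= 2) && any(m$end >= 60))
})

test_that("variant types follow the allele-length table exhaustively", {
  alleles <- c("A", "C", "G", "T",
               as.vector(outer(c("A", "C"), c("A", "G", "T"), paste0)),
               "ATG", "GCC", "TAA", "AT", "GC")
  for (r in alleles) for (a in alleles) {
    if (r == a) next
    got <- classify_type(r, a)
    lr <- nchar(r); la <- nchar(a)
    want <- if (lr == 1 && la == 1) "SNP"
      else if (lr == la) "MNP"
      else if (la > lr && substr(a, 1, lr) == r) "INS"
      else if (lr > la && substr(r, 1, la) == a) "DEL"
      else "COMPLEX"
    expect_identical(got, want, label = paste(r, a))
  }
  expect_identical(classify_type("ATG", "A"), "DEL")
  expect_identical(classify_type("A", "AT"), "INS")
  expect_identical(classify_type("AT", "GCC"), "COMPLEX")
  expect_error(classify_type("AX", "A"), "A/C/G/T/N")
  expect_error(classify_type("A", "A"), "differ")
})

test_that("MNPs decompose into per-base SNPs keyed to their source record", {
  ref <- c(ctgT = "GGATCGATCG")
  cs <- data.frame(contig = "ctgT", pos = 3L, id = "m1", ref = "AT",
                   alt = "GC", vtype = "MNP", stringsAsFactors = FALSE)
  p <- normalize_callset(cs, ref)
  expect_identical(p$pos, c(3L, 4L))
  expect_identical(p$ref, c("A", "T"))
  expect_identical(p$alt, c("G", "C"))
  expect_identical(unique(p$src_id), "m1")
})

test_that("indels left-align through repeat runs to the leftmost anchor", {
  ref <- c(ctgT = "TTCAAAAGG")
  # deleting any single A of the run is the same edit; all placements
  # must normalize identically to the leftmost representation
  edited <- NULL
  for (p in 4:7) {
    cs <- data.frame(contig = "ctgT", pos = p - 1L, id = "d1",
                     ref = substr(ref, p - 1L, p), alt = substr(ref, p - 1L,
                                                               p - 1L),
                     vtype = "DEL", stringsAsFactors = FALSE)
    n <- normalize_callset(cs, ref)
    expect_identical(n$pos, 3L)
    expect_identical(n$ref, "CA")
    expect_identical(n$alt, "C")
    e <- apply_variants_to_seq(ref[[1]], n)
    if (is.null(edited)) edited <- e
    expect_identical(e, edited)
  }
  # insertion into the run also shifts left
  ins <- data.frame(contig = "ctgT", pos = 7L, id = "i1", ref = "A",
                    alt = "AA", vtype = "INS", stringsAsFactors = FALSE)
  n <- normalize_callset(ins, ref)
  expect_identical(n$pos, 3L)
  expect_identical(n$ref, "C")
  expect_identical(n$alt, "CA")
})

test_that("normalization is idempotent and conserves the edited sequence", {
  g <- tiny_genome(seed = 61)
  tv <- plant_variants(g, 300, seed = 7)
  n1 <- normalize_callset(tv, g)
  n2 <- normalize_callset(n1, g)
  expect_identical(n1[, c("contig", "pos", "ref", "alt")],
                   n2[, c("contig", "pos", "ref", "alt")])
  # conservation per contig: originals and primitives produce the same
  # edited sequence (non-overlapping records)
  for (ctg in names(g$contigs)) {
    s1 <- apply_variants_to_seq(g$contigs[[ctg]], tv[tv$contig == ctg, ])
    s2 <- apply_variants_to_seq(g$contigs[[ctg]], n1[n1$contig == ctg, ])
    expect_identical(s1, s2)
  }
  expect_error(
    normalize_callset(data.frame(contig = "ctg001", pos = 5L, id = "bad",
                                 ref = "NNN", alt = "N",
                                 stringsAsFactors = FALSE), g),
    "disagrees")
})

test_that("the filter cascade applies the published thresholds exactly", {
  base <- data.frame(contig = "c1", pos = 100L, id = "v", ref = "A",
                     alt = "G", vtype = "SNP", qual = 60, depth = 20L,
                     alt_fwd = 5L, alt_rev = 5L, stringsAsFactors = FALSE)
  run1 <- function(...) {
    rec <- utils::modifyList(base, list(...))
    apply_filters(as.data.frame(rec), filter_config())
  }
  expect_identical(nrow(run1()$callset), 1L)
  expect_identical(run1(qual = 29.9)$tally[["quality"]], 1L)
  expect_identical(nrow(run1(qual = 30)$callset), 1L)
  expect_identical(run1(depth = 10L)$tally[["min_depth"]], 1L)
  expect_identical(nrow(run1(depth = 11L)$callset), 1L)
  expect_identical(run1(depth = 29L)$tally[["max_depth"]], 1L)
  expect_identical(nrow(run1(depth = 28L)$callset), 1L)
  expect_identical(run1(alt_fwd = 7L, alt_rev = 0L)$tally[["strand"]], 1L)
  expect_identical(run1(depth = NA_integer_)$tally[["malformed"]], 1L)
  # mask removal is attributed first
  cfg <- filter_config(mask = data.frame(contig = "c1", start = 90L,
                                         end = 110L))
  out <- apply_filters(transform(base, qual = 5), cfg)
  expect_identical(out$tally[["mask"]], 1L)
  expect_identical(out$tally[["quality"]], 0L)
  expect_error(filter_config(min_depth = 30, max_depth = 29), "min_depth")
})

test_that("tightening any filter never increases the surviving count", {
  for (k in 1:20) {
    cs <- random_callset(200, seed = k)
    n0 <- nrow(apply_filters(cs, filter_config())$callset)
    expect_lte(nrow(apply_filters(cs, filter_config(min_qual = 40))$callset),
               n0)
    expect_lte(nrow(apply_filters(cs, filter_config(min_depth = 15))$callset),
               n0)
    expect_lte(nrow(apply_filters(cs, filter_config(max_depth = 25))$callset),
               n0)
    expect_lte(
      nrow(apply_filters(cs, filter_config(min_alt_per_strand = 2))$callset),
      n0)
  }
})

test_that("intersection is identity on equal sets and empty on disjoint sets", {
  g <- tiny_genome(seed = 62)
  tv <- plant_variants(g, 200, seed = 8)
  expect_identical(intersect_callsets(tv, tv, g), tv)
  half <- tv[seq_len(100), ]
  other <- tv[101:200, ]
  expect_identical(nrow(intersect_callsets(half, other, g)), 0L)
})

test_that("an MNP is confirmed by its per-base SNPs in the other callset", {
  ref <- c(ctgT = "GGATCGATCG")
  a <- data.frame(contig = "ctgT", pos = 3L, id = "m1", ref = "AT",
                  alt = "GC", vtype = "MNP", stringsAsFactors = FALSE)
  b <- data.frame(contig = "ctgT", pos = c(3L, 4L), id = c("s1", "s2"),
                  ref = c("A", "T"), alt = c("G", "C"), vtype = "SNP",
                  stringsAsFactors = FALSE)
  out <- intersect_callsets(a, b, ref)
  expect_identical(out$id, "m1")
  expect_identical(out$vtype, "MNP")
  # but if one SNP is missing, the MNP is not confirmed
  expect_identical(nrow(intersect_callsets(a, b[1, ], ref)), 0L)
  # and the primitive space of the output is bounded by both inputs
  pa <- normalize_callset(a, ref)
  pb <- normalize_callset(b, ref)
  po <- normalize_callset(out, ref)
  key <- function(x) paste(x$contig, x$pos, x$ref, x$alt)
  expect_true(all(key(po) %in% intersect(key(pa), key(pb))))
})

test_that("three-way comparison matches brute-force set algebra", {
  g <- tiny_genome(seed = 63)
  tv <- plant_variants(g, 300, seed = 9)
  # identical callsets: everything in the center cell
  r <- compare_lines(list(A = tv, B = tv, C = tv), g)
  expect_identical(unname(r$cells[["A:B:C"]]), r$totals[["A"]])
  expect_true(all(r$cells[setdiff(names(r$cells), "A:B:C")] == 0))
  # pairwise-disjoint callsets: only the specific cells
  s <- split(seq_len(300), rep(1:3, each = 100))
  r2 <- compare_lines(list(A = tv[s[[1]], ], B = tv[s[[2]], ],
                           C = tv[s[[3]], ]), g)
  expect_true(all(r2$cells[c("A:B", "A:C", "B:C", "A:B:C")] == 0))
  expect_identical(unname(r2$specific), unname(r2$totals))
  # randomized overlap vs brute force over primitive keys
  set.seed(10)
  pick <- function() tv[sample(300, 150), ]
  sets <- list(A = pick(), B = pick(), C = pick())
  r3 <- compare_lines(sets, g)
  keys <- lapply(sets, function(cs) {
    p <- normalize_callset(cs, g)
    unique(paste(p$contig, p$pos, p$ref, p$alt))
  })
  expect_identical(unname(r3$cells[["A:B:C"]]),
                   length(Reduce(intersect, keys)))
  expect_identical(unname(r3$cells[["A"]]),
                   length(setdiff(keys$A, union(keys$B, keys$C))))
  expect_identical(unname(r3$cells[["A:B"]]),
                   length(setdiff(intersect(keys$A, keys$B), keys$C)))
  # cells of one line sum to its total
  expect_identical(
    unname(r3$cells[["A"]] + r3$cells[["A:B"]] + r3$cells[["A:C"]] +
             r3$cells[["A:B:C"]]),
    unname(r3$totals[["A"]]))
})

test_that("end-to-end: error-free dual callsets recover the truth exactly", {
  g <- tiny_genome(seed = 64)
  tv <- plant_variants(g, 400, seed = 11)
  a <- emulate_callers(tv, g, "JOINED", fp_rate = 0, fn_rate = 0, seed = 12)
  b <- emulate_callers(tv, g, "PRIMITIVE", fp_rate = 0, fn_rate = 0,
                       seed = 13)
  cfg <- filter_config(min_qual = 0, min_depth = 0, max_depth = 10000)
  fa <- apply_filters(a, cfg)$callset
  fb <- apply_filters(b, cfg)$callset
  cons <- intersect_callsets(fa, fb, g)
  expect_identical(cons[, c("contig", "pos", "ref", "alt", "vtype")],
                   tv[, c("contig", "pos", "ref", "alt", "vtype")])
})
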