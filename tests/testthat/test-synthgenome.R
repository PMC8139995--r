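# Generator: determinism, annotation validity, transgenic construction,
# planted spectra, read simulation and caller emulation.

test_that("reference generation is byte-identical for a fixed seed", {
  g1 <- build_reference(n_contigs = 2, contig_len = 50000, seed = 7)
  g2 <- build_reference(n_contigs = 2, contig_len = 50000, seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  a1 <- tempfile(); a2 <- tempfile()
  write_gff3(g1, a1); write_gff3(g2, a2)
  expect_identical(readLines(a1), readLines(a2))
  g3 <- build_reference(n_contigs = 2, contig_len = 50000, seed = 8)
  expect_false(identical(g1$contigs, g3$contigs))
})

test_that("gene density zero yields a gene-free genome", {
  g <- build_reference(n_contigs = 1, contig_len = 12000, gene_density = 0,
                       seed = 1)
  expect_identical(nrow(g$genes), 0L)
  expect_identical(nrow(g$features), 0L)
})

test_that("every emitted CDS length is divisible by 3 (GFF3 scan)", {
  g <- build_reference(seed = 1)
  path <- tempfile(fileext = ".gff3")
  write_gff3(g, path)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  fields <- strsplit(lines, "\t")
  type <- vapply(fields, `[`, "", 3)
  cds <- fields[type == "CDS"]
  tx <- vapply(cds, function(f) sub("^Parent=", "", f[9]), "")
  len <- vapply(cds, function(f) as.integer(f[5]) - as.integer(f[4]) + 1L,
                integer(1))
  per_tx <- tapply(len, tx, sum)
  expect_true(length(per_tx) > 0)
  expect_true(all(per_tx %% 3 == 0))
})

test_that("generated gene models satisfy their structural invariants", {
  g <- build_reference(seed = 3)
  f <- g$features
  # exons sorted and non-overlapping within each transcript
  for (tid in unique(f$transcript_id)) {
    ex <- f[f$transcript_id == tid & f$type == "exon", ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    utr <- f[f$transcript_id == tid & f$type %in%
               c("five_prime_UTR", "three_prime_UTR"), ]
    for (i in seq_len(nrow(utr))) {
      expect_true(any(utr$start[i] >= ex$start & utr$end[i] <= ex$end))
    }
  }
  # every gene inside its contig; canonical transcript exists
  lens <- nchar(g$contigs)
  expect_true(all(g$genes$start >= 1 & g$genes$end <= lens[g$genes$contig]))
  expect_true(all(g$genes$canonical %in% f$transcript_id))
  # at least one overlapping antisense pair
  pair <- g$meta$pair
  ga <- g$genes[g$genes$gene_id == pair$plus_gene, ]
  gb <- g$genes[g$genes$gene_id == pair$minus_gene, ]
  expect_true(ga$strand != gb$strand && ga$start <= gb$end &&
                gb$start <= ga$end)
})

test_that("canonical ORFs translate cleanly from the contig sequence", {
  g <- build_reference(seed = 5)
  pc <- g$genes[g$genes$biotype == "protein_coding", ]
  for (i in seq_len(nrow(pc))) {
    cds <- g$features[g$features$transcript_id == pc$canonical[i] &
                        g$features$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    s <- paste(substring(g$contigs[[pc$contig[i]]], cds$start, cds$end),
               collapse = "")
    if (pc$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_identical(substr(s, 1, 3), "ATG")
    expect_identical(substr(p, nchar(p), nchar(p)), "*")
    expect_false(grepl("\\*.", p))
  }
})

test_that("transgenic length obeys conservation, including a 1304-bp deletion", {
  g <- tiny_genome()
  cons <- tiny_construct()
  tlen <- cons$tdna_end - cons$tdna_start + 1L
  for (d in c(0L, 1304L)) {
    spec <- insertion_spec("ctg001", 15000L, d, 1L, "TDNA_ONLY")
    tg <- build_transgenic_genome(g, cons, spec)
    expect_identical(nchar(tg$contigs[["ctg001"]]),
                     nchar(g$contigs[["ctg001"]]) + tlen - d)
  }
})

test_that("backbone insertions integrate every vector base in two T-DNA copies", {
  g <- tiny_genome()
  cons <- tiny_construct()
  spec <- insertion_spec("ctg002", 14000L, 95L, 2L, "TDNA_BACKBONE_TDNA")
  tg <- build_transgenic_genome(g, cons, spec)
  mut <- tg$contigs[["ctg002"]]
  v <- cons$seq
  tdna <- substr(v, cons$tdna_start, cons$tdna_end)
  # the insert is the plasmid arc between the borders flanked by both
  # T-DNA copies: suffix-from-left-border plus prefix-to-right-border
  expect_true(grepl(substr(v, cons$tdna_start, nchar(v)), mut, fixed = TRUE))
  expect_true(grepl(substr(v, 1, cons$tdna_end), mut, fixed = TRUE))
  expect_identical(tg$insertion$insert_len,
                   nchar(v) + nchar(tdna))
  expect_error(insertion_spec("ctg002", 14000L, 95L, 1L,
                              "TDNA_BACKBONE_TDNA"), "copies = 2")
})

test_that("junctions in protected intervals are rejected", {
  g <- tiny_genome()
  cons <- tiny_construct()
  spec <- insertion_spec("ctg001", 15000L, 100L)
  expect_error(
    build_transgenic_genome(g, cons, spec,
                            protected = data.frame(contig = "ctg001",
                                                   start = 15050L,
                                                   end = 15060L)),
    "protected")
})

test_that("planted variants recover the configured spectrum within 3 s.e.", {
  g <- build_reference(n_contigs = 2, contig_len = 150000, seed = 11)
  n <- 10000L
  tv <- plant_variants(g, n, seed = 3)
  expect_identical(nrow(tv), n)
  # non-overlap: windows 12 bases apart
  by_ctg <- split(tv$pos, tv$contig)
  for (p in by_ctg) expect_true(all(diff(p) >= 12))
  frac <- table(tv$vtype)[names(default_spectrum())] / n
  se <- sqrt(default_spectrum() * (1 - default_spectrum()) / n)
  expect_true(all(abs(frac - default_spectrum()) <= 3 * se))
  # deletion fraction specifically near 62%
  expect_lt(abs(frac[["DEL"]] - 0.62), 3 * se[["DEL"]])
  # types are consistent with alleles
  expect_identical(unname(classify_type(tv$ref, tv$alt)), tv$vtype)
})

test_that("planted SNP transitions match the configured weight (Ts/Tv ~ 1.7)", {
  g <- build_reference(n_contigs = 2, contig_len = 150000, seed = 12)
  tv <- plant_variants(g, 5000, spectrum = c(DEL = 0, SNP = 1, INS = 0,
                                             MNP = 0, COMPLEX = 0),
                       ts_weight = 0.63, seed = 4)
  tt <- ts_tv(tv)
  p_hat <- tt$ts / (tt$ts + tt$tv)
  se <- sqrt(0.63 * 0.37 / 5000)
  expect_lt(abs(p_hat - 0.63), 3 * se)
  expect_lt(abs(tt$ratio - 0.63 / 0.37), 0.2)
})

test_that("plant_variants handles edge inputs", {
  g <- tiny_genome()
  expect_identical(nrow(plant_variants(g, 0, seed = 1)), 0L)
  expect_error(plant_variants(g, 1e6, seed = 1), "too large")
  expect_error(plant_variants(g, 10, spectrum = c(DEL = 0.5, SNP = 0.6,
                                                  INS = 0, MNP = 0,
                                                  COMPLEX = 0), seed = 1),
               "sum to 1")
})

test_that("caller emulation at zero error rates reproduces the truth in both styles", {
  g <- tiny_genome(seed = 21)
  tv <- plant_variants(g, 300, seed = 5)
  for (style in c("JOINED", "PRIMITIVE")) {
    cs <- emulate_callers(tv, g, style, fp_rate = 0, fn_rate = 0, seed = 6)
    pn <- normalize_callset(cs, g)
    pt <- normalize_callset(tv, g)
    expect_identical(pn[, c("contig", "pos", "ref", "alt")],
                     pt[, c("contig", "pos", "ref", "alt")])
  }
  expect_identical(nrow(emulate_callers(tv, g, "JOINED", fn_rate = 1,
                                        seed = 1)), 0L)
})

test_that("emulated true-positive counts follow the binomial law", {
  g <- build_reference(n_contigs = 2, contig_len = 100000, seed = 22)
  tv <- plant_variants(g, 1000, seed = 5)
  # JOINED keeps one record per truth variant (planted variants are
  # spaced, so no adjacent-SNP joins occur)
  cs <- emulate_callers(tv, g, "JOINED", fp_rate = 0.1, fn_rate = 0.1,
                        seed = 5)
  se <- sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(sum(cs$truth) - 900), 3 * se)
  expect_lt(abs(sum(!cs$truth) - 100), 3 * se)
})

test_that("joined style merges adjacent SNPs into an MNP", {
  g <- codon_genome("ATG GCT TGG TAA")
  ref <- c(substring(g$contigs[[1]], 100:102, 100:102),
           substr(g$contigs[[1]], 300, 300))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  truth <- data.frame(contig = "ctgX", pos = c(100L, 101L, 102L, 300L),
                      id = paste0("t", 1:4), ref = ref,
                      alt = unname(rot[ref]), vtype = "SNP",
                      stringsAsFactors = FALSE)
  cs <- emulate_callers(truth, g, "JOINED", seed = 1)
  expect_identical(nrow(cs), 2L)
  expect_identical(cs$vtype[1], "MNP")
  expect_identical(nchar(cs$ref[1]), 3L)
})

test_that("simulated coverage is within 10% of the requested 35x", {
  g <- tiny_genome(seed = 31)
  cons <- tiny_construct()
  tg <- build_transgenic_genome(g, cons, line_fixture_spec(g, "212"))
  sim <- simulate_reads(tg, coverage = 35, read_len = 100, seed = 8)
  depth <- nrow(sim$aln) * 100 / sum(nchar(tg$contigs))
  expect_lt(abs(depth - 35) / 35, 0.10)
})

test_that("error-free reads match their source sequence exactly", {
  g <- tiny_genome(seed = 32)
  sim <- simulate_reads(g, coverage = 2, error_rate = 0, seed = 9)
  idx <- sample(nrow(sim$aln), 50)
  for (i in idx) {
    a <- sim$aln[i, ]
    src <- substr(g$contigs[[a$rname]], a$pos,
                  a$pos + 100 - 1)  # fully genomic, no clipping here
    expect_identical(a$cigar, "100M")
    expect_identical(a$seq, src)
  }
})

test_that("junction-straddling reads are soft-clipped exactly at the junction", {
  g <- tiny_genome(seed = 33)
  cons <- tiny_construct()
  spec <- insertion_spec("ctg001", 15000L, 250L)
  tg <- build_transgenic_genome(g, cons, spec)
  sim <- simulate_reads(tg, coverage = 35, error_rate = 0, seed = 10)
  # reads whose transgenic interval straddles the left junction with the
  # larger part genomic must end their match at left_junction
  orig <- sim$origins
  L <- spec$left_junction
  straddle <- orig$t_contig == "ctg001" & orig$t_start < L - 50 &
    orig$t_end > L
  qn <- orig[straddle, c("qname", "mate")]
  expect_gt(nrow(qn), 0)
  for (k in seq_len(nrow(qn))) {
    mate_bit <- if (qn$mate[k] == 1) 64L else 128L
    a <- sim$aln[sim$aln$qname == qn$qname[k] &
                   bitwAnd(sim$aln$flag, mate_bit) > 0, ]
    expect_identical(a$rname, "ctg001")
    expect_match(a$cigar, "^[0-9]+M[0-9]+S$")
    m <- as.integer(sub("M.*", "", a$cigar))
    expect_equal(a$pos + m - 1L, L)
  }
})

test_that("the truth SAM passes structural validation", {
  g <- tiny_genome(seed = 34)
  cons <- tiny_construct()
  tg <- build_transgenic_genome(g, cons, line_fixture_spec(g, "212"))
  sim <- simulate_reads(tg, coverage = 5, seed = 11)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim, sam)
  # conversion through Rsamtools enforces header/record consistency
  aln2 <- read_alignments(sam)
  expect_identical(nrow(aln2), nrow(sim$aln))
  expect_equal(aln2$pos, sim$aln$pos)
  expect_identical(aln2$cigar, sim$aln$cigar)
  # sorted by coordinate within reference sequence
  for (rn in unique(aln2$rname)) {
    expect_false(is.unsorted(aln2$pos[aln2$rname == rn]))
  }
  # mates paired: every qname appears exactly twice
  expect_true(all(table(aln2$qname) == 2))
  # CIGAR query lengths consistent with sequence lengths
  ql <- vapply(regmatches(aln2$cigar, gregexpr("\\d+(?=[MIS=X])", aln2$cigar,
                                               perl = TRUE)),
               function(x) sum(as.integer(x)), numeric(1))
  expect_identical(as.integer(ql), nchar(aln2$seq))
})

test_that("FASTQ and VCF round-trips preserve the records", {
  g <- tiny_genome(seed = 35)
  tv <- plant_variants(g, 50, seed = 5)
  cs <- emulate_callers(tv, g, "JOINED", seed = 6)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(cs, vcf, nchar(g$contigs))
  back <- read_vcf(vcf)
  expect_identical(back$pos, cs$pos)
  expect_identical(back$ref, cs$ref)
  expect_identical(back$alt, cs$alt)
  expect_identical(back$vtype, cs$vtype)
  expect_identical(back$depth, cs$depth)
  expect_identical(back$alt_fwd, cs$alt_fwd)
  expect_equal(back$qual, cs$qual)
  # GFF3 round trip preserves gene models
  gff <- tempfile(fileext = ".gff3")
  write_gff3(g, gff)
  gm <- read_gff_genes(gff)
  expect_setequal(gm$genes$gene_id, g$genes$gene_id)
  expect_identical(gm$genes$canonical[order(gm$genes$gene_id)],
                   g$genes$canonical[order(g$genes$gene_id)])
  f1 <- gm$features[order(gm$features$transcript_id, gm$features$type,
                          gm$features$start), c("transcript_id", "type",
                                                "start", "end")]
  f2 <- g$features[order(g$features$transcript_id, g$features$type,
                         g$features$start), c("transcript_id", "type",
                                              "start", "end")]
  rownames(f1) <- rownames(f2) <- NULL
  expect_identical(f1, f2)
})
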