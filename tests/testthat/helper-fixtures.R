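# Shared fixtures and independent oracles, all built in code.

tiny_genome <- function(seed = 7, n_contigs = 2, contig_len = 20000,
                        gene_density = 0.8) {
  build_reference(n_contigs = n_contigs, contig_len = contig_len,
                  gene_density = gene_density, seed = seed)
}

tiny_construct <- function(seed = 7) {
  tdna_construct(vector_len = 6000, tdna_start = 1501, tdna_end = 4000,
                 seed = seed)
}

# single-gene genome whose CDS is given codon by codon, e.g.
# codon_genome("ATG GCT TGG TAA"); exact codons let tests target
# start/stop/missense/synonymous changes
codon_genome <- function(codons, strand = "+", seed = 1, flank = 3000) {
  set.seed(seed)
  cds <- gsub(" ", "", codons)
  stopifnot(nchar(cds) %% 3 == 0)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  body <- if (strand == "+") cds else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  contig <- paste0(pad(flank), body, pad(flank))
  s <- flank + 1L
  e <- flank + nchar(cds)
  genes <- data.frame(gene_id = "GX", contig = "ctgX", strand = strand,
                      biotype = "protein_coding", start = s, end = e,
                      canonical = "GX.t1", stringsAsFactors = FALSE)
  features <- data.frame(gene_id = "GX", transcript_id = "GX.t1",
                         contig = "ctgX", strand = strand,
                         type = c("exon", "CDS"), start = s, end = e,
                         stringsAsFactors = FALSE)
  structure(list(contigs = c(ctgX = contig), genes = genes,
                 features = features, chrom_map = NULL, meta = list()),
            class = "toy_genome")
}

# Independent brute-force DUST oracle: scores every subinterval of
# length <= window explicitly with tabulate() over its triplets and
# unions the qualifying ones.
dust_oracle <- function(seq, window = 64, threshold = 20) {
  n <- nchar(seq)
  if (n < 3) return(data.frame(start = integer(), end = integer()))
  b <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  codes <- (b[1:(n - 2)] - 1L) * 16L + (b[2:(n - 1)] - 1L) * 4L + b[3:n]
  masked <- logical(n)
  for (i in 1:(n - 2)) {
    for (j in (i + 2):min(i + window - 1, n)) {
      tri <- codes[i:(j - 2)]
      tri <- tri[!is.na(tri)]
      cnt <- tabulate(tri, 64)
      s <- sum(cnt * (cnt - 1) / 2)
      if (10 * s / (j - i - 1) > threshold) masked[i:j] <- TRUE
    }
  }
  if (!any(masked)) return(data.frame(start = integer(), end = integer()))
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# apply a callset to a sequence (right to left so positions stay valid);
# used for normalization conservation checks
apply_variants_to_seq <- function(seq, callset) {
  cs <- callset[order(-callset$pos), , drop = FALSE]
  for (i in seq_len(nrow(cs))) {
    p <- cs$pos[i]
    seq <- paste0(substr(seq, 1, p - 1L), cs$alt[i],
                  substr(seq, p + nchar(cs$ref[i]), nchar(seq)))
  }
  seq
}

# independent rebuild-translate-diff effect oracle for substitutions
# fully inside the CDS of a gene's canonical transcript
effect_oracle_subst <- function(genome, gene_id, pos, ref, alt) {
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  cds <- genome$features[genome$features$transcript_id == g$canonical &
                           genome$features$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), ]
  plus <- paste(substring(genome$contigs[[g$contig]], cds$start, cds$end),
                collapse = "")
  # CDS index of each genomic position, in transcript orientation
  gpos_all <- unlist(mapply(seq, cds$start, cds$end, SIMPLIFY = FALSE))
  if (g$strand == "-") gpos_all <- rev(gpos_all)
  cds_seq <- if (g$strand == "+") plus else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus)))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mut <- strsplit(cds_seq, "")[[1]]
  rb <- strsplit(ref, "")[[1]]
  ab <- strsplit(alt, "")[[1]]
  for (k in seq_along(rb)) {
    gp <- pos + k - 1L
    idx <- match(gp, gpos_all)
    stopifnot(!is.na(idx))
    mut[idx] <- if (g$strand == "+") ab[k] else comp[[ab[k]]]
  }
  mutseq <- paste(mut, collapse = "")
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p_ref <- tr(cds_seq)
  p_mut <- tr(mutseq)
  n_aa <- nchar(p_ref)
  if (substr(cds_seq, 1, 3) == "ATG" && substr(mutseq, 1, 3) != "ATG") {
    return("start_lost")
  }
  ref_stops <- which(strsplit(p_ref, "")[[1]] == "*")
  mut_stops <- which(strsplit(p_mut, "")[[1]] == "*")
  if (length(setdiff(mut_stops, c(ref_stops, n_aa)))) return("stop_gained")
  if ((n_aa %in% ref_stops) && !(n_aa %in% mut_stops)) return("stop_lost")
  if (p_ref != p_mut) return("missense_variant")
  "synonymous_variant"
}

# random callset with quality/depth/strand fields for filter properties
random_callset <- function(n, seed) {
  set.seed(seed)
  data.frame(
    contig = "c1", pos = sort(sample.int(1e6, n)),
    id = sprintf("r%04d", seq_len(n)),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = "N", vtype = "SNP",
    qual = round(runif(n, 0, 80), 1),
    depth = sample.int(50, n, replace = TRUE),
    alt_fwd = sample(0:10, n, replace = TRUE),
    alt_rev = sample(0:10, n, replace = TRUE),
    stringsAsFactors = FALSE)
}
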