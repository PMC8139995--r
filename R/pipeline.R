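# Orchestration: simulate -> scan -> consensus -> annotate -> summarize,
# each stage standalone over files in the output directory, with a
# seeded config, validation and a checksum manifest.

#' Default pipeline configuration
#'
#' Stage parameter blocks mirror the per-module defaults: 100-bp reads
#' at 35x coverage, minimum variant quality 30, depth strictly between
#' 10 and 29, 1500-bp flanks, 10-kb bins.
#'
#' @param seed top-level integer seed; stage seeds are derived from it.
#' @param outdir output directory.
#' @param line which built-in line fixture to simulate ("212", "224",
#'   "225", or "none" for an insert-free control).
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1, outdir = tempfile("tgpipe"),
                           line = "212") {
  list(
    seed = as.integer(seed), outdir = outdir, line = line,
    genome = list(n_contigs = 2, contig_len = 50000, gene_density = 0.8,
                  gc = 0.35),
    construct = list(vector_len = 9000, tdna_start = 2001, tdna_end = 5000),
    variants = list(n = 800, ts_weight = 0.63, p1_del = 0.975,
                    p1_ins = 0.885, hotspot = NULL),
    reads = list(coverage = 35, read_len = 100, insert_mean = 500,
                 insert_sd = 60, error_rate = 0.001),
    callers = list(fp_rate = 0.02, fn_rate = 0.02, qual_mean = 60,
                   qual_sd = 10, depth_mean = 20),
    scan = list(min_clip = 12, cluster_gap = 1000, min_support = 3,
                promoter_len = 1500),
    filters = list(min_qual = 30, min_depth = 10, max_depth = 29,
                   min_alt_per_strand = 1),
    annot = list(flank = 1500),
    stats = list(bin = 10000, hotspot_threshold = 0.2))
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (see [default_config()]).
#' @return the config, invisibly; stops with the offending key path on
#'   violation.
#' @export
validate_config <- function(config) {
  req <- function(ok, path) if (!ok) stop("invalid config: ", path,
                                          call. = FALSE)
  req(is.numeric(config$seed) && length(config$seed) == 1, "seed")
  req(!is.null(config$outdir), "outdir")
  req(config$line %in% c("212", "224", "225", "none"), "line")
  req(config$genome$contig_len[1] >= 10000, "genome.contig_len")
  req(config$filters$min_depth < config$filters$max_depth,
      "filters.min_depth/max_depth")
  req(config$filters$min_qual >= 0, "filters.min_qual")
  req(config$reads$coverage > 0, "reads.coverage")
  req(config$reads$read_len <= config$reads$insert_mean,
      "reads.read_len/insert_mean")
  req(config$annot$flank >= 0, "annot.flank")
  req(config$stats$bin > 0, "stats.bin")
  invisible(config)
}

#' Read a pipeline configuration from a YAML or JSON file
#' @param path config file; the format is chosen by extension.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  merge <- function(b, o) {
    for (nm in names(o)) {
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(o[[nm]])) {
        merge(b[[nm]], o[[nm]])
      } else o[[nm]]
    }
    b
  }
  merge(base, cfg)
}

.path <- function(config, name) file.path(config$outdir, name)

.need <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  path
}

#' Simulation stage: genome, transgenic line, reads, truth, callsets
#'
#' Writes the reference FASTA, vector FASTA, combined mapping reference,
#' GFF3 gene models, chromosome map, paired FASTQ, truth SAM, truth JSON
#' (insertion, construct, planted variants) and the two emulated caller
#' VCFs (joined and primitive representations).
#'
#' @param config validated configuration.
#' @return paths of the written files, invisibly.
#' @export
stage_simulate <- function(config) {
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  g <- config$genome
  genome <- build_reference(n_contigs = g$n_contigs,
                            contig_len = g$contig_len,
                            gene_density = g$gene_density, gc = g$gc,
                            seed = config$seed)
  cs <- config$construct
  construct <- tdna_construct(vector_len = cs$vector_len,
                              tdna_start = cs$tdna_start,
                              tdna_end = cs$tdna_end,
                              seed = config$seed + 1L)
  if (config$line != "none") {
    spec <- line_fixture_spec(genome, config$line)
    tg <- build_transgenic_genome(genome, construct, spec)
    ins <- tg$insertion
    excl <- data.frame(contig = ins$contig,
                       start = ins$left_junction - 200L,
                       end = ins$right_junction + 200L)
  } else {
    tg <- genome
    ins <- NULL
    excl <- NULL
  }
  vr <- config$variants
  hotspot <- vr$hotspot
  truth <- plant_variants(genome, n = vr$n, ts_weight = vr$ts_weight,
                          p1_del = vr$p1_del, p1_ins = vr$p1_ins,
                          hotspot = hotspot, exclude = excl,
                          seed = config$seed + 2L)
  rd <- config$reads
  sim <- simulate_reads(tg, coverage = rd$coverage, read_len = rd$read_len,
                        insert_mean = rd$insert_mean,
                        insert_sd = rd$insert_sd,
                        error_rate = rd$error_rate,
                        seed = config$seed + 3L)
  ca <- config$callers
  calls_a <- emulate_callers(truth, genome, "JOINED", fp_rate = ca$fp_rate,
                             fn_rate = ca$fn_rate, qual_mean = ca$qual_mean,
                             qual_sd = ca$qual_sd,
                             depth_mean = ca$depth_mean,
                             seed = config$seed + 4L)
  calls_b <- emulate_callers(truth, genome, "PRIMITIVE",
                             fp_rate = ca$fp_rate, fn_rate = ca$fn_rate,
                             qual_mean = ca$qual_mean, qual_sd = ca$qual_sd,
                             depth_mean = ca$depth_mean,
                             seed = config$seed + 5L)

  p <- function(name) .path(config, name)
  write_genome_fasta(genome, p("ref.fasta"))
  write_genome_fasta(stats::setNames(construct$seq, construct$vector_id),
                     p("vector.fasta"))
  write_genome_fasta(genome, p("combined.fasta"), construct = construct)
  write_gff3(genome, p("genes.gff3"))
  write_chrom_map(genome, p("chrom_map.tsv"))
  write_fastq(sim, p("reads"))
  write_sam(sim, p("truth.sam"))
  lens <- nchar(genome$contigs)
  write_vcf(calls_a, p("calls_joined.vcf"), lens)
  write_vcf(calls_b, p("calls_primitive.vcf"), lens)
  jsonlite::write_json(list(
    insertion = ins,
    construct = list(vector_id = construct$vector_id,
                     vector_len = nchar(construct$seq),
                     tdna_start = construct$tdna_start,
                     tdna_end = construct$tdna_end),
    variants = truth), p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list.files(config$outdir, full.names = TRUE))
}

# rebuild the construct object from the truth JSON + vector FASTA
.load_construct <- function(config) {
  tr <- jsonlite::read_json(.need(.path(config, "truth.json")),
                            simplifyVector = TRUE)
  vec <- read_genome_fasta(.need(.path(config, "vector.fasta")))
  structure(list(vector_id = tr$construct$vector_id, seq = unname(vec[1]),
                 tdna_start = tr$construct$tdna_start,
                 tdna_end = tr$construct$tdna_end),
            class = "tdna_construct")
}

.load_genome <- function(config) {
  contigs <- read_genome_fasta(.need(.path(config, "ref.fasta")))
  gm <- read_gff_genes(.need(.path(config, "genes.gff3")))
  cm_path <- .path(config, "chrom_map.tsv")
  cmap <- if (file.exists(cm_path)) read_chrom_map(cm_path) else NULL
  structure(list(contigs = contigs, genes = gm$genes,
                 features = gm$features, chrom_map = cmap, meta = list()),
            class = "toy_genome")
}

#' Insertion-scan stage
#'
#' Reads the truth SAM against the combined reference and writes the
#' called events as TSV and JSON plus the junction intervals as BED.
#'
#' @param config validated configuration.
#' @return the events data frame, invisibly.
#' @export
stage_scan <- function(config) {
  validate_config(config)
  aln <- read_alignments(.need(.path(config, "truth.sam")))
  construct <- .load_construct(config)
  genome <- .load_genome(config)
  lens <- c(nchar(genome$contigs),
            stats::setNames(nchar(construct$seq), construct$vector_id))
  sc <- config$scan
  events <- scan_insertions(aln, construct$vector_id, construct, lens,
                            genome = genome, min_clip = sc$min_clip,
                            cluster_gap = sc$cluster_gap,
                            min_support = sc$min_support,
                            promoter_len = sc$promoter_len)
  write_tsv(events, .path(config, "events.tsv"))
  jsonlite::write_json(events, .path(config, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(events)) {
    bed <- data.frame(contig = events$contig,
                      start = events$left_junction,
                      end = events$right_junction - 1L)
    bed <- bed[!is.na(bed$start) & !is.na(bed$end), , drop = FALSE]
    write_bed(bed, .path(config, "junctions.bed"))
  } else {
    write_bed(data.frame(contig = character(), start = integer(),
                         end = integer()), .path(config, "junctions.bed"))
  }
  invisible(events)
}

#' Consensus stage: mask, normalize, filter, intersect
#'
#' @param config validated configuration.
#' @return the consensus callset, invisibly.
#' @export
stage_consensus <- function(config) {
  validate_config(config)
  ref <- read_genome_fasta(.need(.path(config, "ref.fasta")))
  a <- read_vcf(.need(.path(config, "calls_joined.vcf")))
  b <- read_vcf(.need(.path(config, "calls_primitive.vcf")))
  mask <- dust_mask_genome(ref)
  fc <- config$filters
  cfg <- filter_config(min_qual = fc$min_qual, min_depth = fc$min_depth,
                       max_depth = fc$max_depth,
                       min_alt_per_strand = fc$min_alt_per_strand,
                       mask = mask)
  fa <- apply_filters(a, cfg)
  fb <- apply_filters(b, cfg)
  consensus <- intersect_callsets(fa$callset, fb$callset, ref)
  write_vcf(consensus, .path(config, "consensus.vcf"), nchar(ref))
  write_bed(mask, .path(config, "mask.bed"))
  tally <- data.frame(filter = names(fa$tally), removed_a = as.integer(fa$tally),
                      removed_b = as.integer(fb$tally))
  write_tsv(tally, .path(config, "filter_tally.tsv"))
  invisible(consensus)
}

#' Annotation stage: region, effect and impact per consensus variant
#'
#' @param config validated configuration.
#' @return the annotated callset, invisibly.
#' @export
stage_annotate <- function(config) {
  validate_config(config)
  genome <- .load_genome(config)
  consensus <- read_vcf(.need(.path(config, "consensus.vcf")))
  ann <- annotate_variants(consensus, genome, flank = config$annot$flank)
  write_tsv(ann, .path(config, "annotated.tsv"))
  write_tsv(hi_effect_table(ann), .path(config, "hi_effects.tsv"))
  invisible(ann)
}

#' Summary stage: the per-line statistics report
#'
#' @param config validated configuration.
#' @return the `summary_report`, invisibly.
#' @export
stage_summarize <- function(config) {
  validate_config(config)
  genome <- .load_genome(config)
  consensus <- read_vcf(.need(.path(config, "consensus.vcf")))
  ann_path <- .need(.path(config, "annotated.tsv"))
  ann <- utils::read.table(ann_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  rep_ <- summary_report(consensus, ann, genome,
                         flank = config$annot$flank,
                         bin = config$stats$bin,
                         hotspot_threshold = config$stats$hotspot_threshold)
  write_report_json(rep_, .path(config, "report.json"))
  write_tsv(rep_$bins, .path(config, "bins.tsv"))
  write_tsv(rep_$hotspots, .path(config, "hotspots.tsv"))
  invisible(rep_)
}

#' Run the pipeline
#'
#' Runs the requested stage (or all stages in order) and writes a
#' manifest of every output file with its MD5 checksum; rerunning with
#' the same configuration reproduces identical checksums.
#'
#' @param config a configuration list (see [default_config()]) or the
#'   path of a YAML/JSON config file.
#' @param stage one of "all", "simulate", "scan", "consensus",
#'   "annotate", "summarize".
#' @return the manifest data frame (file, md5), invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stage = c("all", "simulate", "scan", "consensus",
                                   "annotate", "summarize")) {
  if (is.character(config)) config <- read_config(config)
  stage <- match.arg(stage)
  validate_config(config)
  stages <- if (stage == "all") {
    c("simulate", "scan", "consensus", "annotate", "summarize")
  } else stage
  for (s in stages) {
    switch(s,
           simulate = stage_simulate(config),
           scan = stage_scan(config),
           consensus = stage_consensus(config),
           annotate = stage_annotate(config),
           summarize = stage_summarize(config))
  }
  files <- sort(setdiff(list.files(config$outdir, full.names = TRUE),
                        .path(config, "manifest.tsv")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, .path(config, "manifest.tsv"))
  invisible(manifest)
}
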