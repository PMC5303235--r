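#' Run the full workflow into a run directory
#'
#' Executes the enabled stages in order — preprocess, assign, coassemble,
#' authenticate, annotate, c14 — over the inputs named in the configuration,
#' writing machine-readable reports (TSV/FASTA, coordinates 0-based half-open
#' in machine reports) and a JSON manifest recording the configuration hash,
#' seed and package version. Logging goes to stderr.
#'
#' Required inputs in `config$inputs`: `reads_fastq`, `panel_fasta`; for
#' coassembly additionally `ref_ids` (two panel genome ids, prey first); for
#' c14 a `c14_tsv` (label, age, sigma).
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  inp <- config$inputs
  need <- c("reads_fastq", "panel_fasta")
  if (isTRUE(config$stages$c14)) need <- c(need, "c14_tsv")
  for (k in need) {
    if (is.null(inp[[k]]) || !file.exists(inp[[k]]))
      stop("missing input: ", k)
  }
  if (isTRUE(config$stages$coassemble) && length(inp$ref_ids %||% character()) < 2)
    stop("coassembly requires inputs$ref_ids with two genome ids")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[copromito] ", ...)
  res <- list()

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)

  reads <- read_fastq(inp$reads_fastq)
  panel <- read_fasta(inp$panel_fasta)
  params <- aligner_params(err = config$err, miss_thres = config$miss_thres,
                           max_gap_opens = config$max_gap_opens,
                           seed_len = config$seed_len)

  if (isTRUE(config$stages$preprocess)) {
    msg("preprocess: ", nrow(reads), " reads in")
    pp <- preprocess_reads(reads, config$adapter, config$qual_floor,
                           config$min_read_len)
    reads <- pp$reads
    write_tsv(pp$report, file.path(out_dir, "preprocess_report.tsv"))
    res$preprocess <- pp$report
    msg("preprocess: ", nrow(reads), " reads out")
  }

  if (isTRUE(config$stages$assign)) {
    at <- assign_reads(reads, panel, params)
    tab <- at$per_genome
    write_tsv(rbind(tab,
                    data.frame(genome_id = c("__shared__", "__imperfect__",
                                             "__unmapped__"),
                               n_perfect_unique = c(at$n_shared,
                                                    at$n_imperfect_only,
                                                    at$n_unmapped),
                               fraction = NA)),
              file.path(out_dir, "assignment.tsv"))
    res$assign <- at
    msg("assign: top genome ",
        tab$genome_id[which.max(tab$n_perfect_unique)])
  }

  states <- NULL
  if (isTRUE(config$stages$coassemble)) {
    refs <- panel[inp$ref_ids]
    if (any(vapply(refs, is.null, TRUE))) stop("ref_ids not found in panel")
    pcr <- NULL
    if (!is.null(inp$pcr_fasta)) {
      frags <- read_fasta(inp$pcr_fasta, circular = FALSE)
      pcr <- list()
      pcr[[inp$ref_ids[1]]] <- data.frame(
        id = vapply(frags, `[[`, "", "id"),
        sequence = vapply(frags, `[[`, "", "sequence"),
        stringsAsFactors = FALSE)
    }
    co <- iterate_coassembly(reads, refs, params, pcr_fragments = pcr,
                             max_iterations = config$max_iterations,
                             mq_min = config$mq_min, strict = config$mq_strict,
                             min_concordant = config$min_concordant,
                             dispute_frac = config$dispute_frac,
                             damage_window = config$damage_window)
    states <- co$states
    for (id in names(states)) {
      st <- states[[id]]
      write_fasta(setNames(st$sequence, paste0(id, "_consensus")),
                  file.path(out_dir, paste0("consensus_", id, ".fasta")))
      write_tsv(st$gap_report, file.path(out_dir, paste0("gaps_", id, ".bed")))
      write_tsv(data.frame(pos = st$singleton_report),
                file.path(out_dir, paste0("singletons_", id, ".tsv")))
    }
    write_tsv(co$log, file.path(out_dir, "coassembly_log.tsv"))
    res$coassemble <- co
    msg("coassemble: ", co$n_iterations, " iteration(s), converged = ",
        co$converged)
  }

  if (isTRUE(config$stages$authenticate) && !is.null(states)) {
    auth <- list()
    for (id in names(states)) {
      st <- states[[id]]
      panel_now <- lapply(states, function(s)
        reference_genome(s$genome_id, s$sequence))
      aln <- align_reads(reads, panel_now, params)
      excl <- exclusivity_filter(aln, id, setdiff(names(states), id),
                                 mq_min = config$mq_min,
                                 strict = config$mq_strict)
      dd <- dedup_unique(excl)
      if (nrow(dd$alignments) == 0L) next
      prof <- profile_damage(dd$alignments, st$sequence)
      verdict <- authenticity_verdict(prof)
      write_tsv(data.frame(type = rownames(prof$rates3),
                           prof$rates3, check.names = FALSE),
                file.path(out_dir, paste0("damage_3prime_", id, ".tsv")))
      write_tsv(data.frame(type = rownames(prof$rates5),
                           prof$rates5, check.names = FALSE),
                file.path(out_dir, paste0("damage_5prime_", id, ".tsv")))
      auth[[id]] <- data.frame(genome_id = id,
                               identity = prof$identity_fraction,
                               median_length = prof$median_length,
                               verdict = verdict)
      msg("authenticate ", id, ": ", verdict)
    }
    if (length(auth)) {
      summ <- do.call(rbind, auth)
      write_tsv(summ, file.path(out_dir, "authenticity.tsv"))
      res$authenticate <- summ
    }
  }

  if (isTRUE(config$stages$annotate) && !is.null(states)) {
    id <- names(states)[1]
    ref <- panel[[config$inputs$ref_ids[1]]]
    if (!is.null(inp$features_tsv) && file.exists(inp$features_tsv))
      ref$features <- read_tsv(inp$features_tsv)
    if (!is.null(ref$features)) {
      ga <- global_align(states[[id]]$sequence, ref)
      proj <- project_features(ga, ref$features)
      write_tsv(proj, file.path(out_dir, paste0("annotation_", id, ".tsv")))
      res$annotate <- proj
      msg("annotate: ", nrow(proj), " feature(s) projected, edit ", ga$edit)
    }
  }

  if (isTRUE(config$stages$c14)) {
    d <- read_tsv(inp$c14_tsv)
    comb <- combine_dates(d)
    out <- data.frame(label = "combined", age = comb$age, sigma = comb$sigma,
                      method = attr(comb, "method"),
                      T_statistic = attr(comb, "T_statistic"))
    write_tsv(out, file.path(out_dir, "c14_combined.tsv"))
    res$c14 <- comb
    msg("c14: ", comb$age, " +/- ", comb$sigma, " BP")
  }

  manifest <- list(
    package = "copromito",
    version = as.character(utils::packageVersion("copromito")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages_run = names(Filter(isTRUE, config$stages)),
    coordinate_convention = "0-based half-open in machine reports",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
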