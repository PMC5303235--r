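#' Pipeline configuration
#'
#' Builds the full configuration with the workflow's documented defaults:
#' minimum read length 20, mapping-quality gate 25, at least 2 concordant
#' unique sequences per consensus call, 25% dispute threshold, aligner error
#' rate 0.02 with missing-alignment threshold 0.1 and at most 1 gap opening,
#' 500 bootstrap replicates, SNP depth gate 2, and at most 5 assembly
#' iterations.
#'
#' @param ... named overrides of any default; unknown names are an error.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    min_read_len = 20L,
    qual_floor = 2L,
    adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
    err = 0.02,
    miss_thres = 0.1,
    max_gap_opens = 1L,
    seed_len = 9L,
    mq_min = 25L,
    mq_strict = FALSE,
    min_concordant = 2L,
    dispute_frac = 0.25,
    damage_window = 10L,
    max_iterations = 5L,
    bootstrap_reps = 500L,
    min_depth = 2L,
    min_shared = 100L,
    stages = list(preprocess = TRUE, assign = TRUE, coassemble = TRUE,
                  authenticate = TRUE, annotate = TRUE, phylo = FALSE,
                  popgen = FALSE, c14 = FALSE),
    inputs = list()
  )
}

#' @rdname pipeline_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  known <- names(pipeline_config_defaults())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  stopifnot(cfg$min_read_len >= 1, cfg$err > 0, cfg$err < 1,
            cfg$miss_thres > 0, cfg$miss_thres < 1,
            cfg$max_gap_opens %in% 0:2, cfg$mq_min >= 0, cfg$mq_min <= 37,
            cfg$min_concordant >= 1, cfg$dispute_frac > 0, cfg$dispute_frac < 1,
            cfg$max_iterations >= 1, cfg$bootstrap_reps >= 1,
            cfg$min_depth >= 1)
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips exactly: `read_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param cfg a `PipelineConfig`.
#' @param path YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  int_keys <- c("seed", "min_read_len", "qual_floor", "max_gap_opens",
                "seed_len", "mq_min", "min_concordant", "damage_window",
                "max_iterations", "bootstrap_reps", "min_depth", "min_shared")
  for (k in intersect(int_keys, names(cfg))) cfg[[k]] <- as.integer(cfg[[k]])
  validate_config(cfg)
}
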