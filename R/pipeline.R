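#' Run the full probe-design pipeline
#'
#' Executes, in order: candidate tiling on the target chromosome, the
#' repeat-mask filter, the genome-wide uniqueness filter (all
#' chromosomes, both strands), thermodynamic profiling, the dTm screen
#' and density-based selection. Optionally writes the BED6 probe set, a
#' per-oligo thermodynamics TSV, the per-stage survivor report and a
#' JSON run record to an output directory. The default path is fully
#' deterministic: re-running on identical inputs reproduces a
#' byte-identical BED.
#'
#' @param genome a FASTA path or a (list of) [masked_seq]; the whole
#'   assembly, used for the specificity search.
#' @param target_chrom name of the chromosome to design probes for.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; created if missing. On
#'   error any partial outputs in it are removed.
#' @param model a [thermo_model()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_run` with `probe_set`,
#'   `stage_report`, `thermo` (profiled survivors of the uniqueness
#'   stage), `run_record` and, when `out_dir` is given, `paths`.
#' @export
run_pipeline <- function(genome, target_chrom, config = pipeline_config(),
                         out_dir = NULL, model = thermo_model(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  genome_path <- NULL
  if (is.character(genome)) {
    genome_path <- genome
    genome <- read_fasta(genome)
  }
  genome <- genome_as_list(genome)
  names(genome) <- vapply(genome, `[[`, "", "name")
  if (!target_chrom %in% names(genome))
    stop("target chromosome '", target_chrom, "' not found in genome (",
         paste(names(genome), collapse = ", "), ")")
  target <- genome[[target_chrom]]
  say <- function(...) if (!quiet) message(sprintf(...))

  say("tiling %s (%d bp) at %d nt / step %d",
      target_chrom, nchar(target$residues), config$oligo_length, config$step)
  tiled <- tile_candidates(target, config$oligo_length, config$step)
  say("  %d candidates tiled", nrow(tiled))

  unmasked <- mask_filter(tiled, target)
  say("  %d candidates free of masked/ambiguous bases", nrow(unmasked))

  uf <- uniqueness_filter(unmasked, genome,
                          min_identity = config$homology_threshold,
                          exact = config$exact, k = config$seed_k,
                          seed_mm = config$seed_mm)
  unique_cands <- uf$kept
  say("  %d candidates unique genome-wide (%s search)",
      nrow(unique_cands), if (config$exact) "exact" else "seeded")

  profiled <- thermo_profile(unique_cands, model,
                             config$min_stem, config$min_loop)
  kept <- dtm_filter(profiled, config$dtm_min)
  say("  %d candidates with dTm > %g", nrow(kept), config$dtm_min)

  ps <- select_by_density(kept, nchar(target$residues),
                          density_per_kb = config$density_per_kb,
                          target_count = config$target_count,
                          density_basis = config$density_basis,
                          unmasked_length = sum(!target$mask))
  say("  %d probes selected (%d/%d bins filled)", nrow(ps$probes),
      ps$n_bins - length(ps$shortfall_bins), ps$n_bins)

  counts <- c(tiled = nrow(tiled), mask_filter = nrow(unmasked),
              uniqueness_filter = nrow(unique_cands),
              dtm_filter = nrow(kept), selected = nrow(ps$probes))
  report <- stage_report(counts)
  record <- list(
    tool = "probepaint",
    version = as.character(utils::packageVersion("probepaint")),
    config = unclass(config),
    target_chrom = target_chrom,
    genome_path = genome_path,
    genome_digest = if (!is.null(genome_path))
      unname(tools::md5sum(genome_path)) else NULL,
    chrom_length = nchar(target$residues),
    unmasked_length = sum(!target$mask),
    stage_counts = as.list(counts),
    n_shortfall_bins = length(ps$shortfall_bins))

  out <- list(probe_set = ps, stage_report = report, thermo = profiled,
              run_record = record)
  class(out) <- "pipeline_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(bed = file.path(out_dir, "probes.bed"),
               thermo = file.path(out_dir, "thermo.tsv"),
               stages = file.path(out_dir, "stage_report.tsv"),
               record = file.path(out_dir, "run_record.json"))
    tryCatch({
      write_bed(ps, paths[["bed"]])
      data.table::fwrite(
        profiled[, c("chrom", "start", "end", "tm", "hairpin_tm", "dtm")],
        paths[["thermo"]], sep = "\t")
      data.table::fwrite(report, paths[["stages"]], sep = "\t")
      jsonlite::write_json(record, paths[["record"]], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
    }, error = function(e) {
      unlink(paths[file.exists(paths)])
      stop("failed writing outputs: ", conditionMessage(e))
    })
    out$paths <- paths
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$stage_report, row.names = FALSE)
  invisible(x)
}
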