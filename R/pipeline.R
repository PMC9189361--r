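#' Pipeline run configuration
#'
#' Collects every stage's parameters with the global seed. The resolved
#' configuration is written as JSON next to the outputs of every run, so a
#' run can be reproduced from its output directory alone.
#'
#' @param seed Global integer seed; per-stage sub-seeds are derived from it
#'   deterministically.
#' @param promoter,reads,cohort,masks,sections Named lists of per-stage
#'   overrides merged over the defaults (see [run_config_defaults()]).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1, promoter = list(), reads = list(),
                       cohort = list(), masks = list(), sections = list()) {
  defaults <- run_config_defaults()
  merge1 <- function(base, over) utils::modifyList(base, over)
  structure(list(
    seed = as.integer(seed),
    promoter = merge1(defaults$promoter, promoter),
    reads = merge1(defaults$reads, reads),
    cohort = merge1(defaults$cohort, cohort),
    masks = merge1(defaults$masks, masks),
    sections = merge1(defaults$sections, sections)
  ), class = "run_config")
}

#' @rdname run_config
#' @export
run_config_defaults <- function() {
  list(
    promoter = list(length = 2000, n_islands = 3, island_length = 300),
    reads = list(depth = 100, site_probability = 0.7, seq_error_rate = 0,
                 conversion_rate = 1, amplicon_width = 240),
    cohort = list(noise_scale = 1),
    masks = list(n_per_group = 8,
                 groups = list(regular = list(shape = "circle", r = 40),
                               irregular = list(shape = "ellipse", a = 40, b = 20))),
    sections = list(total_depth_px = 120, width_px = 100,
                    lesion_depths_px = c(0, 30, 60, 120))
  )
}

log_stage <- function(level, stage, msg) {
  message(sprintf("[%s] %s %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, stage, msg))
}

config_digest <- function(cfg) {
  unname(tools::md5sum(local({
    f <- tempfile()
    jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
    f
  })))
}

# Returns TRUE if the stage's previous outputs can be reused: the stored
# digest matches and every expected output file still exists.
stage_is_current <- function(out_dir, stage, cfg, outputs) {
  digest_file <- file.path(out_dir, paste0(stage, ".digest"))
  file.exists(digest_file) &&
    identical(readLines(digest_file, warn = FALSE)[1], config_digest(cfg)) &&
    all(file.exists(file.path(out_dir, outputs)))
}

mark_stage <- function(out_dir, stage, cfg) {
  writeLines(config_digest(cfg), file.path(out_dir, paste0(stage, ".digest")))
}

#' Run the pipeline end to end on synthetic data
#'
#' Executes every stage against generated fixtures: promoter simulation and
#' island detection; bisulfite read simulation, alignment, calling and the
#' region methylation rate; cohort simulation with the stage-wise association
#' report and group comparisons; tumor-mask morphometry; and section invasion
#' scoring. All tables are written as TSV, the resolved configuration and a
#' qualitative summary (island count, slope signs, stage-ordering checks) as
#' JSON. Stages whose configuration and outputs are unchanged since the last
#' run in `out_dir` are skipped (checksum-gated resume).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage log messages.
#' @return Invisibly, a list with the stage results and the `summary` list.
#' @export
run_end_to_end <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, msg) if (!quiet) log_stage("INFO", stage, msg)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- stage 1: promoter + methylation calling -----------------------------
  meth_cfg <- config[c("seed", "promoter", "reads")]
  meth_out <- c("promoter.fasta", "islands.bed", "reads.fastq",
                "site_table.tsv", "methylation.json")
  if (stage_is_current(out_dir, "methylation", meth_cfg, meth_out)) {
    say("methylation", "outputs current; skipping")
    meth <- jsonlite::read_json(file.path(out_dir, "methylation.json"))
  } else {
    meth <- tryCatch({
      p <- config$promoter
      region <- do.call(generate_promoter,
                        c(p, list(seed = derive_seed(config$seed, 1))))
      write_promoter_fasta(region, file.path(out_dir, "promoter.fasta"))
      write_islands_bed(region$islands, file.path(out_dir, "islands.bed"), region)
      r <- config$reads
      amp <- if (nrow(region$islands) > 0) {
        amplicon_around_island(region, 1, r$amplicon_width)
      } else {
        subregion(region, 0, min(r$amplicon_width, length(region)))
      }
      prof <- methylation_profile(amp$cpg_sites, r$site_probability)
      reads <- simulate_bisulfite_reads(
        amp, prof, depth = r$depth, seq_error_rate = r$seq_error_rate,
        conversion_rate = r$conversion_rate,
        seed = derive_seed(config$seed, 2))
      write_fastq(reads, file.path(out_dir, "reads.fastq"))
      calls <- call_reads(reads, amp)
      write_site_table(calls, file.path(out_dir, "site_table.tsv"))
      res <- list(islands_detected = nrow(region$islands),
                  n_cpg_sites = length(region$cpg_sites),
                  amplicon_sites = length(amp$cpg_sites),
                  region_rate = methylation_rate(calls),
                  site_probability = r$site_probability)
      jsonlite::write_json(res, file.path(out_dir, "methylation.json"),
                           auto_unbox = TRUE, digits = NA)
      mark_stage(out_dir, "methylation", meth_cfg)
      say("methylation", sprintf("islands = %d, region rate = %.3f",
                                 res$islands_detected, res$region_rate))
      res
    }, error = function(e) {
      abort(sprintf("Stage 'methylation' failed (outputs in %s): %s",
                    out_dir, conditionMessage(e)))
    })
  }

  # --- stage 2: cohort + associations --------------------------------------
  cohort_cfg <- config[c("seed", "cohort")]
  cohort_out <- c("cohort.tsv", "stage_associations.tsv")
  if (stage_is_current(out_dir, "cohort", cohort_cfg, cohort_out)) {
    say("cohort", "outputs current; skipping")
    cohort <- read_cohort_tsv(file.path(out_dir, "cohort.tsv"))
    assoc <- readr::read_tsv(file.path(out_dir, "stage_associations.tsv"),
                             show_col_types = FALSE)
  } else {
    cohort <- simulate_cohort(noise_scale = config$cohort$noise_scale,
                              seed = derive_seed(config$seed, 3))
    write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    assoc <- stage_association_report(cohort)
    readr::write_tsv(as_tibble(assoc), file.path(out_dir, "stage_associations.tsv"))
    mark_stage(out_dir, "cohort", cohort_cfg)
    say("cohort", sprintf("%d/%d slope signs as expected",
                          sum(assoc$sign_ok), nrow(assoc)))
  }
  cmp_meth <- compare_groups(dplyr::filter(cohort, .data$group %in% mm_groups()),
                             meth_rate, group)
  cmp_upa <- compare_groups(dplyr::filter(cohort, .data$group %in% mm_groups()),
                            upa, group)

  # --- stage 3: morphometry ------------------------------------------------
  mask_cfg <- config[c("seed", "masks")]
  if (stage_is_current(out_dir, "morphometry", mask_cfg, "shape_metrics.tsv")) {
    say("morphometry", "outputs current; skipping")
    shapes <- readr::read_tsv(file.path(out_dir, "shape_metrics.tsv"),
                              show_col_types = FALSE)
  } else {
    mk <- config$masks
    masks <- list(); labels <- character(0)
    for (gname in names(mk$groups)) {
      gspec <- mk$groups[[gname]]
      for (i in seq_len(mk$n_per_group)) {
        args <- c(gspec, list(seed = derive_seed(config$seed, 100 + length(masks))))
        masks <- c(masks, list(do.call(generate_tumor_mask, args)))
        labels <- c(labels, gname)
      }
    }
    shapes <- regularity_report(masks, labels)
    readr::write_tsv(as_tibble(shapes), file.path(out_dir, "shape_metrics.tsv"))
    mark_stage(out_dir, "morphometry", mask_cfg)
    say("morphometry", sprintf("%d masks scored", nrow(shapes)))
  }

  # --- stage 4: invasion ---------------------------------------------------
  sect_cfg <- config[c("seed", "sections")]
  if (stage_is_current(out_dir, "invasion", sect_cfg, "invasion.tsv")) {
    say("invasion", "outputs current; skipping")
    invasion <- readr::read_tsv(file.path(out_dir, "invasion.tsv"),
                                show_col_types = FALSE)
  } else {
    sc <- config$sections
    sections <- purrr::map(seq_along(sc$lesion_depths_px), function(i) {
      generate_section(sc$total_depth_px, sc$lesion_depths_px[i], sc$width_px,
                       seed = derive_seed(config$seed, 200 + i))
    })
    names(sections) <- sprintf("section_%02d", seq_along(sections))
    invasion <- invasion_report(sections)
    readr::write_tsv(invasion, file.path(out_dir, "invasion.tsv"))
    mark_stage(out_dir, "invasion", sect_cfg)
    say("invasion", sprintf("%d sections scored", nrow(invasion)))
  }

  # --- summary -------------------------------------------------------------
  mm_means <- cmp_meth$means
  upa_means <- cmp_upa$means
  summary <- list(
    islands_detected = meth$islands_detected,
    islands_expected = config$promoter$n_islands,
    region_rate = meth$region_rate,
    all_slope_signs_ok = all(assoc$sign_ok),
    # Bonferroni over the family of fits in the report
    n_significant_associations = sum(pmin(1, nrow(assoc) * assoc$p_value) < 0.05),
    meth_ordering_ok =
      mm_means$group[1] == "Intraosseous" &&
      mm_means$group[nrow(mm_means)] == "ExtraosseousTumor",
    upa_ordering_ok =
      upa_means$group[1] == "Intraosseous" &&
      upa_means$group[nrow(upa_means)] == "ExtraosseousTumor",
    mean_f_by_group = split(shapes$f_value, shapes$group) |>
      purrr::map(mean),
    relative_invasion = invasion$relative_invasion
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("summary", sprintf("islands %d/%d; slope signs ok: %s",
                         summary$islands_detected, summary$islands_expected,
                         summary$all_slope_signs_ok))
  invisible(list(methylation = meth, cohort = cohort, associations = assoc,
                 shapes = shapes, invasion = invasion, summary = summary))
}
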