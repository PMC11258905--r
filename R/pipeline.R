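#' Run the full marker-discovery pipeline
#'
#' Executes scan -> large-indel screen -> annotate -> depth-rank -> primer
#' design -> e-PCR -> marker catalog on a pair of assemblies and writes
#' every stage's table plus a machine-readable run manifest under
#' `out_dir`. Stages degrade gracefully: without an annotation everything
#' classifies intergenic (logged); without a depth track all markers tier
#' `standard`.
#'
#' @param genome_f,genome_m The two assemblies ([genome]s), female and
#'   male by convention.
#' @param out_dir Output directory (created if missing).
#' @param features Optional feature tibble ([read_gff3()]).
#' @param repeats Optional repeat intervals (tibble `chrom`, `start`,
#'   `end`, optional `genome`).
#' @param depth_track Optional depth track on the female reference
#'   ([read_depth_track()]).
#' @param scan_cfg,primer_par,epcr_par Stage parameter bundles.
#' @param sex_system Which sex is heterogametic.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisibly, a list with the scan object, marker catalog, funnel
#'   and manifest.
#' @export
run_pipeline <- function(genome_f, genome_m, out_dir,
                         features = NULL, repeats = NULL,
                         depth_track = NULL,
                         scan_cfg = scan_config(),
                         primer_par = primer_params(),
                         epcr_par = epcr_params(),
                         sex_system = "male_heterogametic",
                         seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  scan <- bidirectional_scan(genome_f, genome_m, scan_cfg)
  write_variant_catalog(scan$catalog_f,
                        file.path(out_dir, "catalog_female_ref.tsv"))
  write_variant_catalog(scan$catalog_m,
                        file.path(out_dir, "catalog_male_ref.tsv"))
  readr::write_tsv(scan$reconciliation,
                   file.path(out_dir, "reconciliation.tsv"))

  catalog <- scan$catalog_f
  if (is.null(features))
    message("run_pipeline: no annotation supplied; ",
            "all variants classed intergenic")
  ix <- annotation_index(features)
  ann <- tibble::tibble(
    id = catalog$id,
    region_class = classify_point(ix, catalog$ref_chrom,
                                  ifelse(catalog$type == "INS",
                                         catalog$ref_start,
                                         catalog$ref_start)))
  summary_regions <- summarize_regions(catalog, ix)
  readr::write_tsv(summary_regions, file.path(out_dir,
                                              "region_summary.tsv"))
  rep_att <- attribute_repeats(catalog, repeats)
  readr::write_tsv(rep_att$per_variant,
                   file.path(out_dir, "repeat_attribution.tsv"))

  if (!is.null(depth_track)) {
    loci <- locus_depth(depth_track, catalog,
                        chrom_lengths = genome_f$lengths)
    tier_rep <- depth_tier_report(loci)
  } else {
    loci <- tibble::tibble(id = catalog$id, mean_depth = NA_real_,
                           n_bases = NA_integer_)
    tier_rep <- suppressWarnings(
      tier_markers(dplyr::mutate(loci, mean_depth = Inf), NA_real_))
  }
  readr::write_tsv(tier_rep$tiers, file.path(out_dir, "depth_tiers.tsv"))

  primers <- batch_design(genome_f, catalog, primer_par)
  readr::write_tsv(primers, file.path(out_dir, "primers.tsv"))

  epcr_rows <- purrr::map(seq_len(nrow(primers)), function(i) {
    p <- primers[i, ]
    sc <- screen_single_band(p, list(genome_f, genome_m), epcr_par)
    bp <- predict_band_pattern(p, genome_f, genome_m, sex_system, epcr_par)
    tibble::tibble(
      id = p$variant_id, pass = sc$pass, reason = sc$reason,
      bands_female = paste(round(bp$female), collapse = ","),
      bands_male = paste(round(bp$male), collapse = ","),
      diagnostic = bp$diagnostic)
  })
  epcr_res <- dplyr::bind_rows(epcr_rows)
  if (nrow(epcr_res) == 0)
    epcr_res <- tibble::tibble(id = character(), pass = logical(),
                               reason = character(),
                               bands_female = character(),
                               bands_male = character(),
                               diagnostic = logical())
  readr::write_tsv(epcr_res, file.path(out_dir, "epcr_screen.tsv"))

  screened <- epcr_res[epcr_res$pass, , drop = FALSE]
  markers <- build_markers(catalog, ann, primers, epcr_res,
                           tier_rep$tiers[, c("id", "mean_depth", "tier")])
  markers_pass <- markers[markers$pass, , drop = FALSE]
  readr::write_tsv(markers, file.path(out_dir, "marker_catalog.tsv"))

  funnel <- dplyr::bind_rows(lapply(c("INS", "DEL"), function(ty) {
    suppressWarnings(funnel_stats(c(
      scanned = sum(scan$calls_f$type == ty),
      large_indel = sum(catalog$type == ty),
      primer_designed = sum(catalog$id[catalog$type == ty] %in%
                              primers$variant_id),
      single_band = sum(screened$id %in% catalog$id[catalog$type == ty]),
      diagnostic = sum(markers_pass$type == ty & markers_pass$diagnostic)
    ), type = ty))
  }))
  readr::write_tsv(funnel, file.path(out_dir, "funnel.tsv"))

  manifest <- list(
    package = "sexmarkr",
    version = as.character(utils::packageVersion("sexmarkr")),
    seed = seed,
    sex_system = sex_system,
    genomes = list(female = list(label = genome_f$label,
                                 bp = sum(genome_f$lengths)),
                   male = list(label = genome_m$label,
                               bp = sum(genome_m$lengths))),
    config = list(scan = unclass(scan_cfg),
                  primers = unclass(primer_par),
                  epcr = unclass(epcr_par)),
    stage_counts = stats::setNames(as.list(funnel$count),
                                   paste(funnel$type, funnel$stage,
                                         sep = "_")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scan = scan, markers = markers, funnel = funnel,
                 manifest = manifest))
}

#' Run the pipeline from a structured config file
#'
#' The YAML config names the input paths and parameter overrides:
#' `genomes: {female: F.fa, male: M.fa}`, optional `annotation`, `repeats`
#' (BED), `depth` (TSV), `out_dir`, `sex_system`, `seed`, and `scan` /
#' `primers` / `epcr` blocks whose keys override the corresponding
#' parameter constructors.
#'
#' @param path Path to a YAML config file.
#' @return See [run_pipeline()].
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gf <- read_genome_fasta(cfg$genomes$female, label = "female")
  gm <- read_genome_fasta(cfg$genomes$male, label = "male")
  features <- if (!is.null(cfg$annotation)) read_gff3(cfg$annotation)
  repeats <- if (!is.null(cfg$repeats)) read_bed(cfg$repeats)
  depth <- if (!is.null(cfg$depth)) read_depth_track(cfg$depth)
  run_pipeline(
    gf, gm, out_dir = cfg$out_dir %||% "sexmarkr_out",
    features = features, repeats = repeats, depth_track = depth,
    scan_cfg = do.call(scan_config, cfg$scan %||% list()),
    primer_par = do.call(primer_params, cfg$primers %||% list()),
    epcr_par = do.call(epcr_params, cfg$epcr %||% list()),
    sex_system = cfg$sex_system %||% "male_heterogametic",
    seed = cfg$seed %||% 1)
}
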