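# End-to-end orchestration: per-species overlap enrichment, per-chromosome
# membership tallies, scaled boundary distances with the rank-sum
# comparison, and the FISH radial-position report, all driven by one config
# and reproducible from the recorded seed.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Validate a pipeline run configuration
#'
#' A config is a named list with blocks:
#' * `species`: named list; each entry has `features`, `clad`, `cilad`
#'   (BED paths), `chrom_sizes` (path) and optionally `build`,
#'   `features_one_based`.
#' * `enrichment`: `mode` ("feature_count"/"bp"), `n_perm`, `seed`.
#' * `fish` (optional): `alleles` (TSV path, see [read_allele_table()]),
#'   `lamina_thickness`, `lamina_unit`, `group_by` columns.
#'
#' All referenced paths must exist at validation time.
#'
#' @param config named list (e.g. from [yaml::read_yaml()]).
#' @return the validated config, invisibly classed `run_config`.
#' @export
run_config <- function(config) {
  if (is.null(config$species) || length(config$species) == 0)
    stop("config needs at least one species block")
  for (sp in names(config$species)) {
    blk <- config$species[[sp]]
    need <- c("features", "clad", "cilad", "chrom_sizes")
    for (f in need)
      if (is.null(blk[[f]])) stop(sprintf("species '%s' missing '%s'", sp, f))
    for (f in need)
      if (!file.exists(blk[[f]]))
        stop(sprintf("species '%s': path not found: %s", sp, blk[[f]]))
  }
  config$enrichment <- utils::modifyList(
    list(mode = "feature_count", n_perm = 1000, seed = 1), config$enrichment %||% list())
  if (!is.null(config$fish)) {
    config$fish <- utils::modifyList(
      list(lamina_thickness = 0.1, lamina_unit = "um"), config$fish)
    if (!file.exists(config$fish$alleles))
      stop("fish alleles table not found: ", config$fish$alleles)
  }
  structure(config, class = c("run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.unclass_result <- function(r) unclass(r)[c("observed", "expected", "enrichment",
                                            "n_perm", "p_enriched", "p_depleted",
                                            "p_report", "mode")]

#' Run the full comparative analysis
#'
#' For every species block: overlap enrichment of the features against the
#' cLAD and ciLAD sets in both statistic modes, membership fractions and
#' per-chromosome inside/outside counts under both membership rules
#' (any-overlap and midpoint), and scaled boundary distances with a
#' rank-sum comparison of cLAD- vs ciLAD-proximal features. When a `fish`
#' block is present: ND shell histograms per group, a pairwise KS matrix,
#' lamina colocalization and allelic expression summaries. A manifest
#' records the package version, seed and input checksums; re-running the
#' same config and seed reproduces identical outputs.
#'
#' @param config a [run_config()] (or a bare list, validated on entry).
#' @param out_dir output directory (created if needed).
#' @return file manifest (named list of outputs), invisibly.
#' @export
run_all <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  enr_cfg <- config$enrichment
  for (sp in names(config$species)) {
    blk <- config$species[[sp]]
    asm <- with_stage("input", read_chrom_sizes(blk$chrom_sizes,
                                                build = blk$build %||% NA_character_))
    feats <- with_stage("input", read_bed(blk$features, assembly = asm,
                                          one_based = isTRUE(blk$features_one_based)))
    clad <- with_stage("input", domain_set(read_bed(blk$clad, assembly = asm),
                                           "cLAD", asm))
    cilad <- with_stage("input", domain_set(read_bed(blk$cilad, assembly = asm),
                                            "ciLAD", asm))

    enr <- with_stage("enrichment", {
      res <- list()
      for (dom in list(clad, cilad)) for (mode in c("feature_count", "bp"))
        res[[paste(dom$label, mode, sep = ".")]] <- .unclass_result(
          permutation_test(feats, dom, mode = mode, n_perm = enr_cfg$n_perm,
                           seed = enr_cfg$seed))
      res
    })
    outputs[[paste0(sp, ".enrichment")]] <-
      .write_json(enr, file.path(out_dir, paste0(sp, "_enrichment.json")))

    counts <- with_stage("membership", {
      do.call(rbind, lapply(c("any", "midpoint"), function(mode) {
        inside <- features_overlapping(feats, clad, mode = mode)
        chroms <- GenomeInfoDb::seqnames(asm)
        tab_all <- table(factor(as.character(seqnames(feats)), levels = chroms))
        tab_in <- table(factor(as.character(seqnames(inside)), levels = chroms))
        data.frame(mode = mode, chrom = chroms,
                   inside_clad = as.integer(tab_in),
                   outside_clad = as.integer(tab_all) - as.integer(tab_in))
      }))
    })
    outputs[[paste0(sp, ".counts")]] <-
      .write_tsv(counts, file.path(out_dir, paste0(sp, "_clad_counts.tsv")))
    pie <- with_stage("membership", data.frame(
      mode = c("any", "midpoint"),
      frac_in_clad = vapply(c("any", "midpoint"), function(m)
        length(features_overlapping(feats, clad, mode = m)) / length(feats),
        numeric(1))))
    outputs[[paste0(sp, ".membership")]] <-
      .write_tsv(pie, file.path(out_dir, paste0(sp, "_clad_membership.tsv")))

    dists <- with_stage("boundary_distance", {
      rbind(scaled_distance(feats, clad), scaled_distance(feats, cilad))
    })
    outputs[[paste0(sp, ".distances")]] <-
      .write_tsv(dists, file.path(out_dir, paste0(sp, "_scaled_distances.tsv")))
    wil <- with_stage("boundary_distance", {
      a <- dists$scaled[dists$retained & dists$domain_label == "cLAD"]
      b <- dists$scaled[dists$retained & dists$domain_label == "ciLAD"]
      if (length(a) && length(b)) compare_distance_distributions(a, b)
      else list(statistic = NA, p.value = NA, method = "not computed",
                n_a = length(a), n_b = length(b))
    })
    outputs[[paste0(sp, ".wilcoxon")]] <-
      .write_json(wil, file.path(out_dir, paste0(sp, "_wilcoxon.json")))
  }

  if (!is.null(config$fish)) {
    fr <- with_stage("fish", {
      tabs <- read_allele_table(config$fish$alleles)
      nds <- normalized_distance(tabs$alleles, tabs$nuclei)
      grp_cols <- intersect(config$fish$group_by %||% character(0),
                            names(tabs$nuclei))
      grp <- if (length(grp_cols)) {
        i <- match(nds$nucleus_id, tabs$nuclei$nucleus_id)
        interaction(tabs$nuclei[i, grp_cols, drop = FALSE], drop = TRUE)
      } else factor(rep("all", nrow(nds)))
      hists <- do.call(rbind, lapply(levels(grp), function(g) {
        h <- shell_histogram(nds$nd[grp == g])
        data.frame(group = g, shell = 0:9, count = h$counts,
                   fraction = h$fractions)
      }))
      ksm <- list()
      lv <- levels(grp)
      if (length(lv) > 1)
        for (i in seq_len(length(lv) - 1)) for (j in seq(i + 1, length(lv)))
          ksm[[paste(lv[i], lv[j], sep = " vs ")]] <-
            ks_compare(nds$nd[grp == lv[i]], nds$nd[grp == lv[j]])
      coloc <- lamina_colocalization(tabs$alleles, tabs$nuclei,
                                     shell_thickness = config$fish$lamina_thickness,
                                     unit = config$fish$lamina_unit)
      summ <- if (!is.null(tabs$alleles$expressed) &&
                  !is.null(tabs$alleles$locus))
        allelic_summary(tabs$alleles) else NULL
      list(hists = hists, ks = ksm, coloc = coloc, summ = summ)
    })
    outputs[["fish.histograms"]] <-
      .write_tsv(fr$hists, file.path(out_dir, "nd_histograms.tsv"))
    outputs[["fish.ks"]] <- .write_json(fr$ks, file.path(out_dir, "nd_ks.json"))
    outputs[["fish.colocalization"]] <-
      .write_json(fr$coloc, file.path(out_dir, "lamina_colocalization.json"))
    if (!is.null(fr$summ))
      outputs[["fish.allelic"]] <-
        .write_tsv(fr$summ, file.path(out_dir, "allelic_summary.tsv"))
  }

  inputs <- unlist(lapply(config$species, function(b)
    c(b$features, b$clad, b$cilad, b$chrom_sizes)), use.names = FALSE)
  if (!is.null(config$fish)) inputs <- c(inputs, config$fish$alleles)
  manifest <- list(package = "perimir",
                   version = as.character(utils::packageVersion("perimir")),
                   seed = enr_cfg$seed,
                   n_perm = enr_cfg$n_perm,
                   inputs = as.list(tools::md5sum(inputs)),
                   outputs = lapply(outputs, basename))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(outputs)
}

#' Read a YAML/JSON run configuration
#' @param path config file path.
#' @return validated [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  run_config(cfg)
}
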