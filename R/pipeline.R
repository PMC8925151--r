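#' Pipeline configuration
#'
#' A flat, human-editable key/value configuration for the staged pipeline
#' (serialised as YAML; [run_stage()] accepts either this object or a path
#' to such a file, and explicit arguments override file values). Every run
#' writes the resolved configuration next to its outputs, and every
#' artifact carries a header comment with the package version, the
#' configuration hash and the seed.
#'
#' @param input_fasta,samples input paths (filled in by the `simulate`
#'   stage when synthetic data is requested).
#' @param out_dir output directory.
#' @param unit_length,flank5_len,flank3_len see [read_alleles()].
#' @param contact_positions hypervariable amino-acid positions.
#' @param w_mut,w_indel,w_slippage edit-distance weights.
#' @param masked run distance/tree stages on masked sequences.
#' @param dedupe collapse identical arrays before the distance matrix.
#' @param tree_method `"bionj"` or `"nj"`.
#' @param outgroup tip label to root on (`""` leaves the tree unrooted).
#' @param per_variant pooling flag, see [stack_pool()].
#' @param knuckle_count see [name_alleles()].
#' @param motif_window core-motif window, length-2 integer.
#' @param seed seed for the simulate stage.
#' @param quiet suppress progress messages.
#' @param ... overrides for simulation scenario fields, prefixed `sim_`
#'   (e.g. `sim_mu = 1e-5`, `sim_t2 = 1000`).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_fasta = "", samples = "",
                            out_dir = "minisatr_out",
                            unit_length = 84L, flank5_len = 0L,
                            flank3_len = 0L,
                            contact_positions = c(13L, 16L, 19L),
                            w_mut = 1, w_indel = 3.5, w_slippage = 1.75,
                            masked = FALSE, dedupe = TRUE,
                            tree_method = "bionj", outgroup = "",
                            per_variant = FALSE, knuckle_count = 1L,
                            motif_window = c(3L, 6L), seed = 1L,
                            quiet = FALSE, ...) {
  cfg <- list(input_fasta = input_fasta, samples = samples,
              out_dir = out_dir, unit_length = as.integer(unit_length),
              flank5_len = as.integer(flank5_len),
              flank3_len = as.integer(flank3_len),
              contact_positions = as.integer(contact_positions),
              w_mut = w_mut, w_indel = w_indel, w_slippage = w_slippage,
              masked = isTRUE(masked), dedupe = isTRUE(dedupe),
              tree_method = tree_method, outgroup = outgroup,
              per_variant = isTRUE(per_variant),
              knuckle_count = as.integer(knuckle_count),
              motif_window = as.integer(motif_window),
              seed = as.integer(seed), quiet = isTRUE(quiet))
  extra <- list(...)
  bad <- names(extra)[!grepl("^sim_", names(extra))]
  if (length(bad) > 0L)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  structure(c(cfg, extra), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults. The
#' configuration round-trips losslessly through its on-disk form.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  if (!all(c("out_dir", "seed") %in% names(config)))
    stop("not a pipeline configuration")
  config
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

artifact_header <- function(config) {
  sprintf("# minisatr %s config=%s seed=%d",
          as.character(packageVersion("minisatr")),
          config_hash(config), config$seed)
}

log_msg <- function(config, ...) {
  if (!isTRUE(config$quiet))
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

write_artifact <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(artifact_header(config), con)
  close(con)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  path
}

pipeline_inputs <- function(config) {
  read_alleles(config$input_fasta, config$samples,
               unit_length = config$unit_length,
               flank5_len = config$flank5_len,
               flank3_len = config$flank3_len)
}

pipeline_params <- function(config) {
  repeat_dist_params(config$w_mut, config$w_indel, config$w_slippage,
                     masked = config$masked,
                     mask = mask_spec(config$contact_positions,
                                      config$unit_length))
}

scenario_from_config <- function(config) {
  overrides <- config[grepl("^sim_", names(config))]
  names(overrides) <- sub("^sim_", "", names(overrides))
  do.call(sim_scenario, c(list(seed = config$seed), overrides))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (writes synthetic inputs and points the
#' configuration at them), `partition` (unit table), `typezf` (zinc-finger
#' catalogue and named variants), `distmat` (PHYLIP + long-format edit
#' distances), `tree` (Newick, rooted when an outgroup is configured),
#' `diversity` (per-population table), `differentiation` (pairwise Gst and
#' Jost's D), `motifs` (core-motif report) and `all`, which chains them and
#' writes a manifest of artifact checksums. Each stage is idempotent given
#' fixed inputs and seed.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return Named character vector of the artifact paths produced,
#'   invisibly; the updated configuration is attached as attribute
#'   `config` (the `simulate` stage fills in the input paths).
#' @export
run_stage <- function(stage = c("all", "simulate", "partition", "typezf",
                                "distmat", "tree", "diversity",
                                "differentiation", "motifs"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  config <- resolve_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config[!vapply(config, is.null, NA)],
                   file.path(config$out_dir, "config.resolved.yaml"))
  out <- character(0)
  mask <- mask_spec(config$contact_positions, config$unit_length)

  if (stage == "simulate" || (stage == "all" && config$input_fasta == "")) {
    log_msg(config, "simulate: scenario seed ", config$seed)
    sim <- simulate_minisat(scenario_from_config(config))
    paths <- write_sim(sim, config$out_dir)
    config$input_fasta <- paths[["fasta"]]
    config$samples <- paths[["samples"]]
    out <- c(out, paths)
    if (stage == "simulate") {
      attr(out, "config") <- config
      return(invisible(out))
    }
  }
  alleles <- pipeline_inputs(config)

  if (stage %in% c("partition", "all")) {
    log_msg(config, "partition: ", length(alleles), " alleles")
    tab <- unit_table(alleles, contact_positions = config$contact_positions)
    out <- c(out, units = write_artifact(
      tab, file.path(config$out_dir, "units.tsv"), config))
  }
  if (stage %in% c("typezf", "all")) {
    log_msg(config, "typezf")
    cat_tab <- build_catalog(alleles,
                             contact_positions = config$contact_positions)
    out <- c(out, catalog = write_artifact(
      as.data.frame(cat_tab), file.path(config$out_dir, "catalog.tsv"),
      config))
    nm <- name_alleles(alleles, knuckle_count = config$knuckle_count)
    out <- c(out, variants = write_artifact(
      nm$variants, file.path(config$out_dir, "variants.tsv"), config))
    out <- c(out, assignment = write_artifact(
      nm$assignment, file.path(config$out_dir, "variant_assignment.tsv"),
      config))
  }
  if (stage %in% c("distmat", "tree", "all")) {
    params <- pipeline_params(config)
    log_msg(config, "distmat: masked=", params$masked)
    D <- distance_matrix(alleles, params, dedupe = config$dedupe)
    suffix <- if (params$masked) "_masked" else ""
    phy <- file.path(config$out_dir, paste0("distmat", suffix, ".phy"))
    write_phylip(D, phy)
    tsv <- file.path(config$out_dir, paste0("distmat", suffix, ".tsv"))
    write_distance_tsv(D, tsv)
    out <- c(out, distmat_phylip = phy, distmat_tsv = tsv)
    if (stage %in% c("tree", "all")) {
      if (nrow(D) >= 3L) {
        log_msg(config, "tree: ", config$tree_method)
        tr <- nj_tree(D, method = config$tree_method)
        if (nzchar(config$outgroup) && config$outgroup %in% tr$tip.label)
          tr <- root_tree(tr, config$outgroup)
        nwk <- file.path(config$out_dir, paste0("tree", suffix, ".nwk"))
        write_tree_newick(tr, nwk)
        out <- c(out, tree = nwk)
      } else log_msg(config, "tree: skipped (< 3 distinct arrays)")
    }
  }
  if (stage %in% c("diversity", "all")) {
    log_msg(config, "diversity")
    div <- diversity_table(alleles, per_variant = config$per_variant,
                           mask = mask)
    out <- c(out, diversity = write_artifact(
      div, file.path(config$out_dir, "diversity.tsv"), config))
  }
  if (stage %in% c("differentiation", "all")) {
    pops <- unique(vapply(alleles, `[[`, "", "population"))
    if (length(pops) >= 2L) {
      log_msg(config, "differentiation: ", length(pops), " populations")
      rows <- list()
      for (masked in c(FALSE, TRUE)) {
        pools <- lapply(pops, function(p)
          stack_pool(alleles, p, masked = masked,
                     per_variant = config$per_variant, mask = mask))
        d <- differentiation(pools)$pairwise
        d$masked <- masked
        rows[[length(rows) + 1L]] <- d
      }
      out <- c(out, differentiation = write_artifact(
        do.call(rbind, rows),
        file.path(config$out_dir, "differentiation.tsv"), config))
    } else log_msg(config, "differentiation: skipped (single population)")
  }
  if (stage %in% c("motifs", "all")) {
    log_msg(config, "motifs")
    mrep <- motif_report(alleles, window = config$motif_window,
                         knuckle_count = config$knuckle_count)
    out <- c(out, motifs = write_artifact(
      mrep, file.path(config$out_dir, "motifs.tsv"), config))
  }
  if (stage == "all") {
    files <- unname(out)
    manifest <- data.frame(artifact = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    out <- c(out, manifest = write_artifact(
      manifest, file.path(config$out_dir, "manifest.tsv"), config))
  }
  attr(out, "config") <- config
  invisible(out)
}

#' Run the whole pipeline
#'
#' Equivalent to `run_stage("all", config)`: simulates inputs when none are
#' configured, then chains partition, typing, distances, tree, diversity,
#' differentiation and motifs, writing a checksum manifest.
#'
#' @inheritParams run_stage
#' @return See [run_stage()].
#' @export
run_pipeline <- function(config = pipeline_config()) {
  run_stage("all", config)
}
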