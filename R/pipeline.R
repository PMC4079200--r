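#' Run the full analysis pipeline on a simulated scenario
#'
#' Orchestrates simulate -> find -> date -> tree -> mosaic -> htscan with a
#' single configuration and one root seed (expanded per stage), writing
#' stage outputs and a reproducibility manifest to `out_dir`. Stages whose
#' outputs already exist are skipped unless `force = TRUE`, so deleting a
#' late-stage output and re-running recomputes only downstream work.
#'
#' @param config Either a [sim_config()] or a path to a YAML file with its
#'   fields (plus optional `host_divergence` table rows and stage switches
#'   `run_find`, `run_tree`, `run_htscan`).
#' @param out_dir Output directory (created if needed).
#' @param host_tbl Optional [host_table()]; required when the HT scan is
#'   enabled. Validated before any compute.
#' @param boot_reps Bootstrap replicates for dating/tree stages.
#' @param force Recompute stages whose outputs already exist.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, host_tbl = NULL, boot_reps = 100L,
                         force = FALSE) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    host_tbl <- if (!is.null(y$host_divergence))
      host_table(do.call(rbind.data.frame, y$host_divergence)) else host_tbl
    ht_events <- if (!is.null(y$ht_events))
      do.call(rbind.data.frame, y$ht_events) else NULL
    config <- sim_config(
      host_tree = y$host_tree %||% "(A:50,B:50);",
      n_subfamilies = y$n_subfamilies %||% 2L,
      transposition_rate = y$transposition_rate %||% 0.2,
      omega = y$omega %||% 0.2,
      genome_length = y$genome_length %||% 30000L,
      ht_events = ht_events, seed = y$seed %||% 1L)
  }
  stopifnot(inherits(config, "sim_config"))
  do_htscan <- !is.null(config$ht_events) || !is.null(host_tbl)
  if (do_htscan && is.null(host_tbl))
    stop("htscan enabled but no host divergence table supplied")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), root_seed = config$seed)
  stage_done <- function(files) !force && all(file.exists(files))
  log_stage <- function(name, params, files) {
    manifest$stages[[name]] <<- list(
      name = name, parameters = params,
      seed = stage_seed(config$seed, name),
      outputs = as.list(tools::md5sum(files)))
  }

  # -- simulate ---------------------------------------------------------
  f_el <- file.path(out_dir, "elements.fasta")
  f_truth <- file.path(out_dir, "truth.tsv")
  f_genome <- file.path(out_dir, "genomes.fasta")
  sim <- simulate_cr(config)
  if (!stage_done(c(f_el, f_truth, f_genome))) {
    write_fasta(setNames(vapply(sim$elements, function(e) e$seq,
                                character(1)),
                         vapply(sim$elements, function(e) e$id,
                                character(1))), f_el)
    write.table(sim$truth, f_truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_fasta(sim$genomes, f_genome)
  }
  log_stage("simulate", list(n_subfamilies = config$n_subfamilies,
                             rate = config$transposition_rate,
                             omega = config$omega),
            c(f_el, f_truth, f_genome))

  # -- find -------------------------------------------------------------
  f_found <- file.path(out_dir, "found_elements.tsv")
  if (!stage_done(f_found)) {
    rows <- list()
    for (h in names(sim$genomes)) {
      query <- sim$elements[[which(sim$truth$host == h)[1]]]$seq
      found <- call_full_length(sim$genomes[[h]], query,
                                contig = h, host = h, id_prefix = h)
      for (e in found)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = e$genome_location$contig, start = e$genome_location$start,
          end = e$genome_location$end, strand = e$genome_location$strand,
          id = e$id, stringsAsFactors = FALSE)
    }
    found_df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(contig = character(0), start = integer(0),
                 end = integer(0), strand = character(0), id = character(0))
    write.table(found_df, f_found, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  log_stage("find", unclass(finder_params()), f_found)

  # -- date -------------------------------------------------------------
  f_ages <- file.path(out_dir, "insertion_ages.tsv")
  if (!stage_done(f_ages)) {
    at <- age_table(sim$elements, config$rates, boot_reps = boot_reps,
                    seed = stage_seed(config$seed, "date"))
    write.table(at$elements, f_ages, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  log_stage("date", list(r_intergenic = config$rates$r_intergenic,
                         boot_reps = boot_reps), f_ages)

  # -- tree (per subfamily alignment with >= 4 members) -----------------
  f_tree <- file.path(out_dir, "trees.nwk")
  if (!stage_done(f_tree)) {
    trees <- list()
    for (nm in names(sim$alignments)) {
      al <- sim$alignments[[nm]]
      if (length(al) < 4L) next
      trees[[nm]] <- bootstrap_support(al, n_reps = 100L,
                                       seed = stage_seed(config$seed, nm))
    }
    if (length(trees)) {
      cls <- lapply(trees, unclass)
      tl <- structure(cls, class = "multiPhylo")
      ape::write.tree(tl, file = f_tree)
    } else writeLines(character(0), f_tree)
  }
  log_stage("tree", list(model = "t3p", boot = 100L), f_tree)

  # -- htscan -----------------------------------------------------------
  f_ht <- file.path(out_dir, "ht_candidates.tsv")
  if (do_htscan && !stage_done(f_ht)) {
    pd <- element_pair_divergences(sim, boot_reps = 0L)
    cand <- ht_scan(pd, host_tbl)
    ht_report(cand, f_ht)
  }
  if (do_htscan)
    log_stage("htscan", list(mild = 1.5, extreme = 3.0, ratio = 0.5), f_ht)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Cross-host element divergence times from a simulation result
#'
#' For every subfamily and host pair, estimates the synonymous distance of
#' the two hosts' master elements over the polyprotein ORF and converts it
#' to a divergence time — the per-pair input that [ht_scan()] consumes.
#'
#' @param sim A [simulate_cr()] result.
#' @param rate Synonymous rate /site/yr.
#' @param boot_reps Bootstrap replicates for the dS standard error.
#' @param seed RNG seed.
#' @return Data frame with `pair`, `host_a`, `host_b`, `t_ma`, `se_ma`,
#'   `ks`, `omega`.
#' @export
element_pair_divergences <- function(sim, rate = NULL, boot_reps = 0L,
                                     seed = NULL) {
  rates <- sim$config$rates
  if (is.null(rate)) rate <- rates$r_synonymous
  dm <- sim$template$domain_map
  orf <- dm$ORF
  masters <- sim$truth$origin == "master"
  rows <- list()
  for (r in seq_len(nrow(sim$pair_truth))) {
    pt <- sim$pair_truth[r, ]
    ia <- which(masters & sim$truth$subfamily == pt$subfamily &
                  sim$truth$host == pt$host_a)[1]
    ib <- which(masters & sim$truth$subfamily == pt$subfamily &
                  sim$truth$host == pt$host_b)[1]
    if (is.na(ia) || is.na(ib)) next
    oa <- substr(sim$elements[[ia]]$seq, orf[1] + 1L, orf[2])
    ob <- substr(sim$elements[[ib]]$seq, orf[1] + 1L, orf[2])
    cd <- nei_gojobori(oa, ob, boot_reps = boot_reps,
                       seed = if (is.null(seed)) NULL else seed + r)
    age <- divergence_age(cd$dS, cd$se_dS, rate = rate)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = sprintf("CR%d:%s/%s", pt$subfamily, pt$host_a, pt$host_b),
      host_a = pt$host_a, host_b = pt$host_b,
      t_ma = age$t_ma, se_ma = age$se_ma, ks = cd$dS, omega = cd$omega,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Summarize pipeline outputs as markdown
#'
#' Tabulates per-subfamily copy numbers and age ranges, HT candidates and
#' (when present) mosaic calls from a pipeline output directory.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param path Optional file to write the markdown to.
#' @return Character vector of markdown lines, invisibly when `path` given.
#' @export
pipeline_report <- function(out_dir, path = NULL) {
  lines <- c("# retroclock pipeline report", "")
  f_ages <- file.path(out_dir, "insertion_ages.tsv")
  if (file.exists(f_ages)) {
    ages <- read.delim(f_ages)
    lines <- c(lines, "## Insertion ages by subfamily", "",
               "| subfamily | copies | min Ma | mean Ma | max Ma |",
               "|---|---|---|---|---|")
    for (g in split(ages, ages$subfamily))
      lines <- c(lines, sprintf("| %s | %d | %.3f | %.3f | %.3f |",
                                g$subfamily[1], nrow(g),
                                suppressWarnings(min(g$t_ma, na.rm = TRUE)),
                                mean(g$t_ma, na.rm = TRUE),
                                suppressWarnings(max(g$t_ma, na.rm = TRUE))))
    lines <- c(lines, "")
  }
  f_ht <- file.path(out_dir, "ht_candidates.tsv")
  if (file.exists(f_ht)) {
    ht <- read.delim(f_ht)
    lines <- c(lines, "## Horizontal-transfer candidates", "")
    if (nrow(ht) == 0L) lines <- c(lines, "no candidates", "")
    else lines <- c(lines,
                    sprintf("- %s: element divergence %.2f Ma vs host %.2f Ma (%s)",
                            ht$pair, ht$t_ma, ht$host_divergence_ma,
                            ht$outlier_class), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
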