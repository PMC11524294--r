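# End-to-end orchestration: simulate -> call -> annotate -> enrich ->
# cluster -> motif, with a manifest of hashes/counts per stage, plus
# verification of the bundled worked-example fixtures.

#' Default pipeline run configuration
#'
#' A flat list: a seed, an output directory, the stages to run, the
#' synthetic-generator settings and every analysis threshold.  Serialize /
#' restore with [write_run_config()] / [read_run_config()].
#'
#' @param outdir output directory.
#' @param seed integer seed driving all randomness.
#' @param stages character subset of
#'   c("simulate","call","annotate","enrich","cluster","motif").
#' @param sim named list of overrides for [sim_config()] (seed is taken
#'   from the run config).
#' @param min_coverage,alpha caller thresholds.
#' @param rho_threshold,cluster_alpha coexpression thresholds.
#' @param motif_window,purine_threshold,motif_min_sites motif-scan
#'   settings.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(outdir = tempfile("nucredit_run_"), seed = 1L,
                       stages = c("simulate", "call", "annotate",
                                  "enrich", "cluster", "motif"),
                       sim = list(),
                       min_coverage = 50L, alpha = 0.05,
                       rho_threshold = 0.7, cluster_alpha = 0.05,
                       motif_window = 5L, purine_threshold = 0.6,
                       motif_min_sites = 20L) {
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 sim = sim, min_coverage = as.integer(min_coverage),
                 alpha = alpha, rho_threshold = rho_threshold,
                 cluster_alpha = cluster_alpha,
                 motif_window = as.integer(motif_window),
                 purine_threshold = purine_threshold,
                 motif_min_sites = as.integer(motif_min_sites)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
  cfg
}

stage_paths <- function(outdir) {
  file.path(outdir, c(
    fasta = "transcripts.fasta", gff3 = "regions.gff3",
    pileup = "pileup.tsv", truth = "truth.tsv",
    expression = "expression.tsv", roles = "roles.tsv",
    labels = "labels.tsv",
    sites = "sites.tsv", annotated = "annotated.tsv",
    summary = "summary.json", enrichment = "enrichment.tsv",
    endo = "endosymbiont_test.json",
    clusters = "clusters.tsv", motif = "motif_report.tsv",
    manifest = "manifest.json"
  )) |> setNames(c("fasta", "gff3", "pileup", "truth", "expression",
                   "roles", "labels", "sites", "annotated", "summary",
                   "enrichment", "endo", "clusters", "motif", "manifest"))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order under \code{config}.
#' Every stage writes its outputs under \code{config$outdir}; the manifest
#' (also written as \code{manifest.json}) records output hashes, row
#' counts and wall time per stage, so identical configs yield identical
#' manifests.  A disabled stage whose outputs are required downstream must
#' have been produced by a previous run in the same directory.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return the manifest, invisibly (list of class \code{run_manifest}).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(config$outdir)
  manifest <- list(parameters = unclass(config), stages = list())
  policy <- read_filter_policy(min_coverage = config$min_coverage,
                               alpha = config$alpha)
  need <- function(p, stage) {
    if (!file.exists(p))
      stop("stage '", stage, "' needs missing input: ", p)
    p
  }
  note <- function(stage, outputs, rows, t0) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(unname(tools::md5sum(outputs))) |>
        setNames(basename(outputs)),
      rows = rows,
      seconds = round(as.numeric(Sys.time()) - t0, 2))
  }
  skip_note <- function(stage) manifest$stages[[stage]] <<- "skipped"

  if ("simulate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    tx <- generate_transcripts(scfg)
    planted <- plant_sites(tx, scfg)
    emb <- embed_motif_context(tx, planted, scfg)
    tx <- emb$transcripts
    pu <- simulate_pileup(tx, planted, scfg)
    expr <- simulate_expression(scfg)
    labs <- simulate_annotations(scfg)
    write_transcripts(tx, paths["fasta"], paths["gff3"])
    write_pileup(pu, paths["pileup"])
    write_truth(planted, paths["truth"])
    write_expression(expr, paths["expression"])
    write.table(attr(expr, "roles"), paths["roles"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_labels(labs, paths["labels"])
    note("simulate",
         paths[c("fasta", "gff3", "pileup", "truth", "expression",
                 "roles", "labels")],
         c(transcripts = nrow(tx), planted = nrow(planted),
           pileup_columns = nrow(pu), genes = nrow(expr),
           labels = nrow(labs)), t0)
  } else skip_note("simulate")

  if ("call" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    tx <- read_transcripts(need(paths["fasta"], "call"),
                           need(paths["gff3"], "call"))
    pu <- read_pileup(need(paths["pileup"], "call"), tx)
    calls <- call_editing_sites(pu, policy)
    write_sites(calls, paths["sites"])
    note("call", paths["sites"], c(sites = nrow(calls)), t0)
  } else skip_note("call")

  if ("annotate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    tx <- read_transcripts(need(paths["fasta"], "annotate"),
                           need(paths["gff3"], "annotate"))
    sites <- read_sites(need(paths["sites"], "annotate"))
    ann <- annotate_sites(sites, tx)
    write_sites(ann, paths["annotated"])
    summ <- list(
      n_sites = nrow(ann),
      type_by_codon_position = if (nrow(ann)) as.data.frame(
        table(type = ann$type_label, codon_position = ann$codon_position))
      else NULL,
      synonymy = if (nrow(ann))
        as.list(table(ann$synonymous, useNA = "ifany")) else NULL,
      density = density_table(ann, tx),
      amino_acid_rates = amino_acid_rates(ann),
      groups = group_transcripts(ann)$summary
    )
    jsonlite::write_json(summ, paths["summary"], auto_unbox = TRUE,
                         digits = NA)
    note("annotate", paths[c("annotated", "summary")],
         c(annotated = nrow(ann)), t0)
  } else skip_note("annotate")

  if ("enrich" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    labs <- read_labels(need(paths["labels"], "enrich"))
    enr <- go_enrichment(labs, alpha = config$alpha)
    ef <- endosymbiont_fisher(labs)
    write.table(enr, paths["enrichment"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(table = ef$table, odds_ratio = ef$odds_ratio,
           p_value = ef$p_value, fraction_endo = ef$fraction_endo,
           fraction_other = ef$fraction_other),
      paths["endo"], auto_unbox = TRUE, digits = NA)
    note("enrich", paths[c("enrichment", "endo")],
         c(significant_terms = nrow(enr)), t0)
  } else skip_note("enrich")

  if ("cluster" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    expr <- read_expression(need(paths["expression"], "cluster"))
    degrees <- numeric(0)
    if (file.exists(paths["annotated"])) {
      ann <- read_sites(paths["annotated"])
      ctu <- ann[ann$type_label == "C-to-U", , drop = FALSE]
      if (nrow(ctu))
        degrees <- tapply(ctu$degree, ctu$transcript_id, mean)
    }
    adj_expr <- adjust_expression(expr, degrees)
    net <- spearman_network(adj_expr, config$rho_threshold,
                            config$cluster_alpha)
    cl <- decompose_scm(net, config$cluster_alpha)
    memb <- if (length(cl$clusters)) do.call(rbind, lapply(
      seq_along(cl$clusters), function(i) {
        m <- cl$clusters[[i]]
        data.frame(cluster_id = i, gene_id = m$members,
                   join_order = seq_along(m$members))
      })) else data.frame(cluster_id = integer(), gene_id = character(),
                          join_order = integer())
    write.table(memb, paths["clusters"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("cluster", paths["clusters"],
         c(clusters = length(cl$clusters), assigned = nrow(memb)), t0)
  } else skip_note("cluster")

  if ("motif" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    tx <- read_transcripts(need(paths["fasta"], "motif"),
                           need(paths["gff3"], "motif"))
    ann <- read_sites(need(paths["annotated"], "motif"))
    ctu <- ann[ann$type_label == "C-to-U", , drop = FALSE]
    rep_rows <- NULL
    if (nrow(ctu) >= config$motif_min_sites) {
      ms <- motif_scan(ctu, tx, window = config$motif_window,
                       purine_threshold = config$purine_threshold,
                       min_sites = config$motif_min_sites)
      rep_rows <- cbind(
        ms$tests,
        t(ms$composition$counts[, as.character(ms$tests$position)]))
      rep_rows$core <- ms$core
    }
    if (is.null(rep_rows))
      rep_rows <- data.frame(position = integer(), chi2 = numeric(),
                             df = integer(), p_value = numeric())
    write.table(rep_rows, paths["motif"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("motif", paths["motif"], c(positions_tested = nrow(rep_rows)), t0)
  } else skip_note("motif")

  class(manifest) <- "run_manifest"
  # wall time excluded from the serialized manifest so identical configs
  # hash identically
  ser <- manifest
  ser$stages <- lapply(ser$stages, function(s) {
    if (is.list(s)) s$seconds <- NULL
    s
  })
  jsonlite::write_json(unclass(ser), paths["manifest"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$stages), "stages\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    if (identical(st, "skipped")) cat("  ", s, ": skipped\n")
    else cat("  ", s, ": ", paste(names(st$rows), st$rows, sep = "=",
                                  collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
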