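# End-to-end orchestration: config validation, per-class analysis
# (expression distances, ML distances + NJ tree + bootstrap + cophenetic,
# Dn/Ds table), divergence test suite, and report serialization.

#' Validate a pipeline configuration
#'
#' Checks a configuration (list or JSON path) and returns either the
#' validated config or stops with every violation found, not just the
#' first.
#'
#' Required fields: `classes` (named list; each with `codon_fasta` path),
#' `expression_tsv`. Optional: `model` (`kind`, `alpha`, `p_inv`, `k`),
#' `boot_n`, `n_perm`, `seed`, `tail`, `genetic_source`
#' (`"cophenetic"` or `"pairwise"`), `out_dir`.
#'
#' @param config list or path to JSON
#' @return validated config list (class `pipeline_config`)
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    base_dir <- dirname(config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    # resolve relative paths against the config file location
    fix <- function(p) if (!is.null(p) && !file.exists(p) &&
                           file.exists(file.path(base_dir, p)))
      file.path(base_dir, p) else p
    config$expression_tsv <- fix(config$expression_tsv)
    for (k in seq_along(config$classes)) {
      config$classes[[k]]$codon_fasta <- fix(config$classes[[k]]$codon_fasta)
    }
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  known <- c("classes", "expression_tsv", "model", "boot_n", "n_perm",
             "seed", "tail", "genetic_source", "out_dir", "t_max")
  extra <- setdiff(names(config), known)
  if (length(extra)) note(paste0("unknown config keys: ",
                                 paste(extra, collapse = ", ")))
  if (is.null(config$classes) || !length(config$classes) ||
      is.null(names(config$classes))) {
    note("classes: required named list is missing or unnamed")
  } else {
    for (cls in names(config$classes)) {
      cf <- config$classes[[cls]]$codon_fasta
      if (is.null(cf)) note(sprintf("classes.%s.codon_fasta: missing", cls))
      else if (!file.exists(cf)) note(sprintf("classes.%s.codon_fasta: no such file '%s'",
                                              cls, cf))
    }
  }
  if (is.null(config$expression_tsv)) {
    note("expression_tsv: missing")
  } else if (!file.exists(config$expression_tsv)) {
    note(sprintf("expression_tsv: no such file '%s'", config$expression_tsv))
  }
  defaults <- list(model = list(kind = "GTR", alpha = 1, p_inv = 0, k = 4),
                   boot_n = 100L, n_perm = 999L, seed = 1L, tail = "one",
                   genetic_source = "cophenetic", t_max = 10)
  config <- utils::modifyList(defaults, config)
  config$model <- utils::modifyList(defaults$model, as.list(config$model))
  if (!config$model$kind %in% c("JC69", "GTR", "JTT")) {
    note(sprintf("model.kind: '%s' is not one of JC69/GTR/JTT",
                 config$model$kind))
  }
  if (!config$genetic_source %in% c("cophenetic", "pairwise")) {
    note(sprintf("genetic_source: '%s' is not 'cophenetic' or 'pairwise'",
                 config$genetic_source))
  }
  if (!config$tail %in% c("one", "two")) note("tail: must be 'one' or 'two'")
  # cross-reference: each expression gene id in at most one class
  if (!length(problems) || is.null(config$gene_class_overlap_checked)) {
    ids_by_class <- list()
    for (cls in names(config$classes)) {
      cf <- config$classes[[cls]]$codon_fasta
      if (!is.null(cf) && file.exists(cf)) {
        ids_by_class[[cls]] <- tryCatch(read_codon_fasta(cf)$ids,
                                        error = function(e) character(0))
      }
    }
    all_ids <- unlist(ids_by_class, use.names = FALSE)
    dup <- unique(all_ids[duplicated(all_ids)])
    if (length(dup)) note(paste0("gene id(s) claimed by more than one class: ",
                                 paste(dup, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the end-to-end divergence analysis
#'
#' Per class: reads the codon alignment, computes expression correlation
#' distances (after row scaling), the ML distance matrix under the
#' configured model, the NJ tree with bootstrap supports, cophenetic
#' distances, and the Dn/Ds pair table; then runs the within- and
#' between-class divergence test suite. Class failures are isolated: the
#' run errors only when every class fails.
#'
#' @param config a validated [validate_config] result (or something
#'   coercible by it)
#' @return list of class `run_report`: `classes` (per-class artifacts),
#'   `divergence` (the [run_divergence_suite] report), `failed`
#'   (per-class error messages), `provenance`
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  expr_all <- read_expression_tsv(config$expression_tsv)
  model <- subst_model(config$model$kind, alpha = config$model$alpha,
                       p_inv = config$model$p_inv, k = config$model$k)
  class_art <- list(); failed <- list(); class_dists <- list()
  for (cls in names(config$classes)) {
    res <- tryCatch({
      aln <- read_codon_fasta(config$classes[[cls]]$codon_fasta)
      genes <- intersect(aln$ids, rownames(expr_all))
      if (length(genes) < 3L) {
        stop("fewer than 3 genes shared between alignment and expression table")
      }
      aln <- aln_subset(aln, genes)
      scaled <- scale_rows(expr_all[genes, , drop = FALSE])
      expr_d <- correlation_distance(scaled)
      gen_pairwise <- ml_distance_matrix(aln, model, config$t_max)
      tree <- bootstrap_support(aln, model, n_boot = config$boot_n,
                                seed = config$seed)
      gen_d <- if (config$genetic_source == "cophenetic")
        cophenetic_dist(tree) else gen_pairwise
      kaks <- pairwise_kaks_table(aln)
      list(alignment = aln, expression_scaled = scaled,
           expression_dist = expr_d, ml_dist = gen_pairwise,
           tree = tree, genetic_dist = gen_d,
           kaks_table = kaks$table, omega_dist = kaks$omega_dist,
           dendrogram = cluster_centroid(expr_d))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed[[cls]] <- res
    } else {
      class_art[[cls]] <- res
      class_dists[[cls]] <- list(genetic = res$genetic_dist,
                                 expression = res$expression_dist,
                                 omega = res$omega_dist)
    }
  }
  if (!length(class_art)) {
    stop("all classes failed:\n  ",
         paste(names(failed), unlist(failed), sep = ": ", collapse = "\n  "),
         call. = FALSE)
  }
  divergence <- run_divergence_suite(class_dists, n_perm = config$n_perm,
                                     seed = config$seed, tail = config$tail)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  structure(list(classes = class_art, divergence = divergence,
                 failed = if (length(failed)) failed else NULL,
                 provenance = list(
                   config = unclass(config),
                   config_md5 = unname(tools::md5sum(tf)),
                   seeds = list(bootstrap = config$seed,
                                permutation = config$seed),
                   package_version = as.character(utils::packageVersion("dupliverge")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "run_report")
}

#' Write a run report to disk
#'
#' Emits per-class TSV artifacts (distance matrices, Dn/Ds table, tree with
#' supports, dendrogram), the divergence test tables, a JSON summary with
#' full numeric precision, a manifest with md5 checksums of every written
#' file, and a log of all seeds.
#'
#' @param report a `run_report` from [run_analysis]
#' @param dir output directory (created if missing)
#' @return invisibly, the manifest data.frame
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit_tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  for (cls in names(report$classes)) {
    art <- report$classes[[cls]]
    p <- function(suffix) file.path(dir, paste0(cls, "_", suffix))
    write_dist_tsv(art$expression_dist, p("expression_dist.tsv"))
    write_dist_tsv(art$ml_dist, p("ml_dist.tsv"))
    write_dist_tsv(art$genetic_dist, p("genetic_dist.tsv"))
    write_dist_tsv(art$omega_dist, p("omega_dist.tsv"))
    write_newick(art$tree, p("tree.nwk"))
    write_dendrogram(art$dendrogram, p("expression_dendrogram.nwk"),
                     p("expression_merges.tsv"))
    emit_tsv(art$kaks_table, paste0(cls, "_kaks.tsv"))
    files <- c(files, p("expression_dist.tsv"), p("ml_dist.tsv"),
               p("genetic_dist.tsv"), p("omega_dist.tsv"), p("tree.nwk"),
               p("expression_dendrogram.nwk"), p("expression_merges.tsv"))
  }
  dv <- report$divergence
  if (!is.null(dv$within)) emit_tsv(dv$within, "within_class_tests.tsv")
  if (!is.null(dv$summary)) emit_tsv(dv$summary, "class_summary.tsv")
  if (!is.null(dv$between)) emit_tsv(dv$between, "between_class_tests.tsv")
  if (!is.null(dv$skipped)) emit_tsv(dv$skipped, "skipped_tests.tsv")
  summary_json <- list(
    within = dv$within, summary = dv$summary, between = dv$between,
    skipped = dv$skipped, failed = report$failed,
    provenance = report$provenance)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(summary_json, json_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  files <- c(files, json_path)
  log_path <- file.path(dir, "run.log")
  writeLines(c(
    sprintf("config_md5: %s", report$provenance$config_md5),
    sprintf("package_version: %s", report$provenance$package_version),
    sprintf("r_version: %s", report$provenance$r_version),
    sprintf("timestamp: %s", report$provenance$timestamp),
    sprintf("seed_bootstrap: %s", report$provenance$seeds$bootstrap),
    sprintf("seed_permutation: %s", report$provenance$seeds$permutation),
    sprintf("classes_ok: %s", paste(names(report$classes), collapse = ",")),
    sprintf("classes_failed: %s",
            paste(names(report$failed), collapse = ","))), log_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
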