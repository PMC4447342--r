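#' Read an expression matrix from tab-delimited text
#'
#' Expects a header of sample ids and a first column of gene ids. Duplicate
#' gene ids, missing values and non-numeric cells are rejected with the
#' offending coordinates; Windows line endings are tolerated.
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("parse error in ", path,
                         ": need a gene-id column plus samples")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric or missing cell in ", path, " at gene '",
         genes[bad[1, 1]], "', sample '", colnames(vals)[bad[1, 2]], "'")
  dimnames(num) <- list(genes, colnames(df)[-1])
  num
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are serialized with 17 significant digits so a write/read
#' round-trip reproduces the doubles exactly.
#'
#' @param mat genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  txt <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  df <- data.frame(gene_id = rownames(mat), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the gene-annotation flags table
#'
#' Tab-delimited with columns `gene_id`, `secreted_annotation`, `receptor`,
#' `growth_factor`, `detected_in_cm` (0/1 or logical).
#'
#' @param path file path.
#' @return data frame with logical flag columns.
#' @export
load_flags <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "secreted_annotation", "receptor", "growth_factor",
            "detected_in_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("flags table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  for (cl in need[-1]) df[[cl]] <- as.logical(as.integer(df[[cl]]))
  df[need]
}

#' @rdname load_flags
#' @param flags flags data frame.
#' @export
write_flags <- function(flags, path) {
  out <- flags
  for (cl in setdiff(names(out), "gene_id"))
    out[[cl]] <- as.integer(out[[cl]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with the reference defaults. Inputs may be
#' in-memory matrices/data frames or file paths (TSV, as written by the
#' package's own writers).
#'
#' @param stromal,tumor,controls expression matrices or paths.
#' @param flags gene-annotation data frame or path.
#' @param q_max,lfc_min DE thresholds.
#' @param network_total stromal network size handed to
#'   [select_network_genes()].
#' @param alpha PC test level.
#' @param n_runs,subsample_size,top_fraction,freq_threshold stability
#'   selection settings.
#' @param mgsa an `mgsa_params` object or `NULL` for defaults.
#' @param b posterior threshold of [select_regulators()].
#' @param seed master seed; stage seeds are derived from it.
#' @param outdir optional output directory for artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stromal, tumor, controls, flags,
                            q_max = 0.001, lfc_min = 1.0,
                            network_total = 2000, alpha = 0.2,
                            n_runs = 100, subsample_size = NULL,
                            top_fraction = 0.30, freq_threshold = 0.7,
                            mgsa = NULL, b = 0.5, seed = 1L,
                            outdir = NULL) {
  stopifnot(q_max > 0, q_max < 1, lfc_min >= 0, alpha > 0, alpha < 1,
            top_fraction > 0, top_fraction <= 1,
            freq_threshold >= 0, freq_threshold <= 1, b >= 0, b <= 1)
  structure(list(stromal = stromal, tumor = tumor, controls = controls,
                 flags = flags, q_max = q_max, lfc_min = lfc_min,
                 network_total = network_total, alpha = alpha,
                 n_runs = n_runs, subsample_size = subsample_size,
                 top_fraction = top_fraction,
                 freq_threshold = freq_threshold, mgsa = mgsa, b = b,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

resolve_matrix <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    tryCatch(load_expression(x),
             error = function(e) stop("[", what, "] ", conditionMessage(e),
                                      call. = FALSE))
  } else if (is.matrix(x)) x
  else stop("[", what, "] expected a matrix or a file path", call. = FALSE)
}

#' Run the full causal paracrine-discovery pipeline
#'
#' Orchestrates, under a single master seed: differential expression of
#' stimulated versus control tumor samples and strict target selection; the
#' secreted-candidate cascade and network-gene selection on the stromal
#' matrix; subsampled PC + IDA stability selection; target-set construction
#' and MGSA condensation to the final regulator table. When
#' `config$outdir` is set every intermediate artifact is written as TSV/JSON
#' and their md5 hashes recorded.
#'
#' @param config a `pipeline_config`.
#' @return list of class `pipeline_report` with the stage outputs, survivor
#'   counts, parameters, wall time, and (for file inputs) input hashes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 2L)

  log_stage <- function(...) message("[paracausal] ", ...)

  log_stage("loading inputs")
  stromal <- resolve_matrix(config$stromal, "preprocess")
  tumor <- resolve_matrix(config$tumor, "preprocess")
  controls <- resolve_matrix(config$controls, "preprocess")
  flags <- if (is.character(config$flags)) {
    tryCatch(load_flags(config$flags),
             error = function(e) stop("[preprocess] ", conditionMessage(e),
                                      call. = FALSE))
  } else config$flags
  if (!is.data.frame(flags)) stop("[preprocess] flags must be a data frame or path")
  input_hashes <- c(stromal = file_hash(config$stromal),
                    tumor = file_hash(config$tumor),
                    controls = file_hash(config$controls),
                    flags = file_hash(config$flags))

  log_stage("differential expression (", ncol(tumor), " stimulated vs ",
            ncol(controls), " controls)")
  de <- moderated_t_test(tumor, controls)
  targets <- select_target_genes(de, q_max = config$q_max,
                                 lfc_min = config$lfc_min)
  if (length(targets) < 2)
    stop("[preprocess] fewer than 2 differentially expressed target genes")

  log_stage("gene selection cascade")
  candidates <- select_secreted_candidates(stromal, flags)
  if (length(candidates) < 1)
    stop("[preprocess] no secreted candidates survive the cascade")
  network <- select_network_genes(stromal, candidates,
                                  total = min(config$network_total,
                                              nrow(stromal)))

  log_stage("stability selection (", config$n_runs, " runs, alpha = ",
            config$alpha, ")")
  stab <- stability_selection(stromal[network, , drop = FALSE],
                              tumor, candidates, targets,
                              alpha = config$alpha, n_runs = config$n_runs,
                              subsample_size = config$subsample_size,
                              top_fraction = config$top_fraction,
                              freq_threshold = config$freq_threshold,
                              seed = stage_seeds[1])

  log_stage("regulator condensation (MGSA)")
  retained <- retained_effects(stab)
  coll <- build_target_sets(retained, universe = targets)
  regulator_table <- NULL
  selected <- character()
  if (length(coll$sets)) {
    prm <- config$mgsa %||% mgsa_params(n_sets = length(coll$sets),
                                        seed = stage_seeds[2])
    if (is.null(prm$seed)) prm$seed <- stage_seeds[2]
    regulator_table <- mgsa_mcmc(coll, observed = targets, params = prm)
    selected <- select_regulators(regulator_table, b = config$b)
  }

  report <- structure(list(
    de = de, targets = targets, candidates = candidates,
    network_genes = network, stability = stab, target_sets = coll,
    regulator_table = regulator_table, regulators = selected,
    counts = list(
      de_targets = length(targets),
      cascade = attr(candidates, "audit"),
      network_genes = length(network),
      retained_pairs = nrow(retained),
      regulator_sets = length(coll$sets),
      selected_regulators = length(selected)),
    params = config[!(names(config) %in%
                        c("stromal", "tumor", "controls", "flags"))],
    seed = config$seed, stage_seeds = stage_seeds,
    input_hashes = input_hashes,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pipeline_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

file_hash <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    unname(tools::md5sum(x)) else NA_character_
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Causal paracrine-discovery pipeline report\n",
      "  DE targets: ", x$counts$de_targets,
      "; secreted candidates: ", length(x$candidates),
      "; network genes: ", x$counts$network_genes, "\n",
      "  retained (x, y) pairs: ", x$counts$retained_pairs,
      " -> ", x$counts$regulator_sets, " regulator sets\n",
      "  selected regulators: ",
      paste(x$regulators, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Serialize every pipeline artifact; all outputs are re-loadable by the
# package's own readers.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  de_path <- file.path(outdir, "de_table.tsv")
  write.table(report$de, de_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(report$targets, file.path(outdir, "target_genes.txt"))
  writeLines(report$candidates, file.path(outdir, "secreted_candidates.txt"))
  writeLines(report$network_genes, file.path(outdir, "network_genes.txt"))
  write.table(report$stability$table,
              file.path(outdir, "stable_effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$regulator_table))
    write.table(report$regulator_table,
                file.path(outdir, "regulator_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(counts = report$counts,
                  params = report$params[!vapply(report$params, is.null,
                                                 logical(1))],
                  seed = report$seed,
                  input_hashes = as.list(report$input_hashes),
                  wall_time_s = report$wall_time_s,
                  regulators = report$regulators,
                  artifact_hashes = as.list(tools::md5sum(
                    list.files(outdir, pattern = "\\.(tsv|txt)$",
                               full.names = TRUE))))
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(outdir)
}

#' Serialize a CPDAG as an edge list plus separating sets
#'
#' @param x a `cpdag`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cpdag <- function(x, dir) {
  stopifnot(inherits(x, "cpdag"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cpdag_edges(x), file.path(dir, "cpdag_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$sepsets, file.path(dir, "sepsets.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}
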