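# End-to-end pipeline: ingest -> phams -> ANI -> clustering -> gene-content
# matrix/tree -> diversity, with every stage's outputs written before the
# next begins and a manifest that makes the run auditable and reproducible.

#' Configuration for a pipeline run
#'
#' @param input Input genomes: a directory containing `.gbk`/`.gb`/`.fasta`
#'   files, a character vector of such files, or a list of [genome()]
#'   objects.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed covers any stochastic inputs built from it).
#' @param pham A [pham_params()].
#' @param ani An [ani_params()].
#' @param clustering A [clustering_params()].
#' @param metric Gene-content distance metric.
#' @param external Optional path to an external reference protein FASTA
#'   (`[genus=...]` header tags), or a data.frame as from
#'   [read_external_fasta()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, out_dir, seed = 1L,
                       pham = pham_params(), ani = ani_params(),
                       clustering = clustering_params(),
                       metric = "jaccard", external = NULL) {
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 pham = pham, ani = ani, clustering = clustering,
                 metric = metric, external = external),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override the corresponding defaults of
#' [run_config()]; parameter sub-maps (`pham:`, `ani:`, `clustering:`)
#' override individual parameter defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$input) || is.null(y$out_dir)) {
    stop("config must provide 'input' and 'out_dir'")
  }
  run_config(
    input = y$input, out_dir = y$out_dir, seed = y$seed %||% 1L,
    pham = do.call(pham_params, y$pham %||% list()),
    ani = do.call(ani_params, y$ani %||% list()),
    clustering = do.call(clustering_params, y$clustering %||% list()),
    metric = y$metric %||% "jaccard", external = y$external
  )
}

.ingest <- function(input) {
  if (is.list(input) && all(vapply(input, inherits, TRUE, "genome"))) {
    return(.as_genome_list(input))
  }
  files <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.(gbk?|genbank|fa|fasta|fna)$",
               full.names = TRUE)
  } else as.character(input)
  if (!length(files)) stop("no input genome files found")
  files <- sort(files, method = "radix")
  is_gbk <- grepl("\\.(gbk?|genbank)$", files)
  out <- list()
  for (f in files[is_gbk]) {
    g <- read_genbank(f)
    if (!is.null(out[[g$id]])) stop("duplicate genome id '", g$id, "' in inputs")
    out[[g$id]] <- g
  }
  # FASTA records whose id already arrived as an annotated GenBank record
  # are skipped (the annotated record wins)
  for (f in files[!is_gbk]) {
    for (g in read_fasta(f)) {
      if (is.null(out[[g$id]])) out[[g$id]] <- g
    }
  }
  .as_genome_list(out)
}

#' Run the full comparative-genomics pipeline
#'
#' Stages, in order: ingest, per-genome metrics, pham construction
#' (plus external attachment when configured), all-pairs ANI, cluster
#' assignment, presence/absence matrix with NEXUS and newick exports, and
#' the diversity report. Each stage's TSV outputs are written to
#' `config$out_dir` before the next stage begins; a failure aborts with a
#' stage-labelled error, leaving earlier outputs in place. Re-running the
#' same configuration on the same inputs reproduces byte-identical outputs.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return An object of class `phamlin_result` bundling all stage outputs
#'   and the manifest.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done (%.1fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }

  genomes <- stage("ingest", .ingest(config$input))
  if (length(genomes) < 2L) stop("pipeline requires >= 2 genomes")

  metrics <- stage("metrics", genome_metrics_table(genomes))
  f <- file.path(out, "metrics.tsv")
  write.table(metrics, f, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, f)

  phams <- stage("phams", {
    proteins <- collect_proteins(genomes)
    pt <- build_phams(proteins, config$pham)
    if (!is.null(config$external)) {
      ext <- if (is.character(config$external)) {
        read_external_fasta(config$external)
      } else config$external
      pt <- attach_external(pt, ext, proteins)
    }
    pt
  })
  artifacts <- c(artifacts, write_pham_tsv(phams, file.path(out, "phams.tsv")))

  ani <- stage("ani", ani_matrix(genomes, config$ani))
  artifacts <- c(artifacts, write_ani_tsv(ani, file.path(out, "ani.tsv")),
                 write_ani_tsv(ani, file.path(out, "aligned_fraction.tsv"),
                               "aligned_fraction"))

  assignment <- stage("cluster",
                      assign_clusters(genomes, ani, phams, config$clustering))
  artifacts <- c(artifacts,
                 write_clusters_tsv(assignment, file.path(out, "clusters.tsv")))

  pm <- stage("gene_content", presence_matrix(phams, names(genomes)))
  f <- file.path(out, "presence_matrix.tsv")
  write.table(data.frame(genome = rownames(pm), pm, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, f,
                 export_nexus(pm, file.path(out, "phams.nex")))
  dists <- gene_content_distance(pm, config$metric)
  tree <- nj_tree(dists)
  f <- file.path(out, "tree.nwk")
  ape::write.tree(tree, f)
  artifacts <- c(artifacts, f)

  diversity <- stage("diversity", diversity_report(assignment, phams))
  f <- file.path(out, "diversity.tsv")
  write.table(diversity, f, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, f)

  manifest <- list(
    tool = "phamlin", version = as.character(packageVersion("phamlin")),
    seed = config$seed,
    inputs = if (is.list(config$input)) {
      list(kind = "in-memory genomes", ids = names(genomes))
    } else {
      fl <- if (length(config$input) == 1L && dir.exists(config$input)) {
        list.files(config$input, full.names = TRUE,
                   pattern = "\\.(gbk?|genbank|fa|fasta|fna)$")
      } else as.character(config$input)
      list(kind = "files",
           files = data.frame(path = fl, md5 = unname(tools::md5sum(fl)),
                              stringsAsFactors = FALSE))
    },
    parameters = list(pham = unclass(config$pham), ani = unclass(config$ani),
                      clustering = unclass(config$clustering),
                      metric = config$metric),
    artifacts = artifacts
  )
  f <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  artifacts <- c(artifacts, f)

  structure(list(genomes = genomes, metrics = metrics, phams = phams,
                 ani = ani, assignment = assignment, presence = pm,
                 distances = dists, tree = tree, diversity = diversity,
                 manifest = manifest, config = config),
            class = "phamlin_result")
}

#' @export
print.phamlin_result <- function(x, ...) {
  cat(sprintf("<phamlin_result> %d genomes -> %d phams -> %d clusters + %d singletons\n",
              length(x$genomes), length(x$phams$phams),
              length(x$assignment$clusters), length(x$assignment$singletons)))
  cat("  outputs in ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}

#' @export
summary.phamlin_result <- function(object, ...) {
  cat("Genomes:\n")
  print(object$metrics, row.names = FALSE)
  cat("\nClusters:\n")
  print(object$assignment)
  cat("\nPhams: ", length(object$phams$phams), " (",
      length(orphams(object$phams)), " orphams)\n\nDiversity:\n", sep = "")
  print(as.data.frame(object$diversity), row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.phamlin_result <- function(x, ...) {
  plot(x$diversity, ...)
  invisible(x)
}

#' Render a run report
#'
#' A single Markdown document with the per-genome metrics table, cluster
#' table, diversity table and a full parameter echo. Regeneration from the
#' same result is idempotent.
#'
#' @param result A `phamlin_result` from [run_all()].
#' @param path Optional output path; when `NULL` the text is returned only.
#' @return Invisibly, the report text (character vector of lines).
#' @export
report <- function(result, path = NULL) {
  stopifnot(inherits(result, "phamlin_result"))
  if (is.null(result$diversity) || is.null(result$assignment)) {
    stop("incomplete run: missing stage outputs")
  }
  md_table <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 4, format = "fg"))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste0("| ", paste(as.character(unlist(df[i, ])), collapse = " | "), " |")
      }, ""))
  }
  cl <- result$assignment$assignment
  lines <- c(
    "# phamlin run report", "",
    sprintf("- genomes: %d", length(result$genomes)),
    sprintf("- phams: %d (%d orphams)", length(result$phams$phams),
            length(orphams(result$phams))),
    sprintf("- clusters: %d; singletons: %d",
            length(result$assignment$clusters),
            length(result$assignment$singletons)),
    "", "## Genome metrics", "", md_table(result$metrics),
    "", "## Cluster assignment", "", md_table(cl),
    "", "## Diversity", "", md_table(result$diversity),
    "", "## Parameters", "",
    "```json",
    strsplit(as.character(jsonlite::toJSON(result$manifest$parameters,
                                           auto_unbox = TRUE, pretty = TRUE,
                                           digits = NA)), "\n")[[1]],
    "```"
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
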