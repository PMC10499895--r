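.CONFIG_KEYS <- c("catalog", "tracks", "cluster_regions", "window_width",
                  "vicinity", "enzymes", "oligos", "qpcr_curves",
                  "max_product_size", "seed", "simulate")

#' Read and validate a pipeline run configuration
#'
#' YAML or JSON with keys: `catalog` (TSV path), `tracks` (named list of
#' track file paths), `cluster_regions` (list of `[start, end]` pairs),
#' `window_width`, `vicinity`, `enzymes`, `oligos`, `qpcr_curves` (file
#' paths), `max_product_size`, `seed`, `simulate` (list with `n`).
#' Unknown keys are rejected; referenced files must exist. Missing keys
#' fall back to the packaged defaults.
#'
#' @param config path to a YAML/JSON file, or a config list.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config$catalog <- config$catalog %||%
    fusionbreak_example("breakpoint_catalog.tsv")
  config$enzymes <- config$enzymes %||%
    fusionbreak_example("lri_enzymes.tsv")
  config$oligos <- config$oligos %||% fusionbreak_example("oligos.tsv")
  config$qpcr_curves <- config$qpcr_curves %||%
    fusionbreak_example("qpcr_standard_curves.csv")
  config$window_width <- config$window_width %||% 40L
  config$vicinity <- config$vicinity %||% 30L
  config$max_product_size <- config$max_product_size %||% 10000L
  config$seed <- config$seed %||% 1L
  if (is.null(config$cluster_regions)) {
    cr <- pbx1_cluster_regions()
    config$cluster_regions <- lapply(seq_len(nrow(cr)), function(i)
      c(cr$start[i], cr$end[i]))
  }
  for (f in c(config$catalog, config$enzymes, config$oligos,
              config$qpcr_curves, unlist(config$tracks)))
    if (!file.exists(f)) stop("config references missing file: ", f,
                              call. = FALSE)
  structure(config, class = c("run_config", "list"))
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order and writes a JSON
#' report per stage (plus TSV side outputs) into a run directory named by
#' the config hash. Every report embeds the config hash and seed;
#' deterministic stages are byte-identical across reruns of the same
#' config.
#'
#' Stages: `catalog` (load + summarize), `clusters` (sliding-window and
#' fixed-region statistics on the catalog), `overlap` (annotation-track
#' classification, when `tracks` are configured), `qpcr` (efficiency
#' recomputation from the standard-curve table), `simulate` (synthetic
#' cohort with truth table).
#'
#' @param config a [read_run_config()] input.
#' @param stages character subset of stages (empty vector: do nothing).
#' @param out_dir parent directory for the run directory (default tempdir).
#' @return named list of stage reports (also written as JSON), invisibly.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("catalog", "clusters", "qpcr"),
                         out_dir = tempdir()) {
  known <- c("catalog", "clusters", "overlap", "qpcr", "simulate")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  config <- read_run_config(config)
  hash <- .config_hash(config)
  run_dir <- file.path(out_dir, paste0("run-", substr(hash, 1, 12)))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config_hash = hash, seed = config$seed)
  reports <- list()

  need_catalog <- length(intersect(stages,
                                   c("catalog", "clusters", "overlap"))) > 0
  cat49 <- if (need_catalog) load_catalog(config$catalog) else NULL

  if ("catalog" %in% stages) {
    s <- catalog_summary(cat49)
    reports$catalog <- c(meta, list(
      n_patients = s$n_patients, sex = as.list(s$sex),
      phenotype = as.list(s$phenotype), sample_type = as.list(s$sample_type),
      age = s$age,
      breaks = list(TCF3 = sum(cat49$breaks$gene == "TCF3"),
                    PBX1 = sum(cat49$breaks$gene == "PBX1"))))
  }

  if ("clusters" %in% stages) {
    tc <- breakpoints(cat49, gene = "TCF3")
    win <- max_coverage_window(tc$position, config$window_width,
                               ids = tc$patient_id)
    regions <- do.call(rbind, lapply(seq_along(config$cluster_regions),
      function(i) region(config$cluster_regions[[i]][1],
                         config$cluster_regions[[i]][2],
                         paste0("cluster", i))))
    pb <- breakpoints(cat49, gene = "PBX1")
    counts <- count_in_regions(pb, regions)
    in_regions <- sum(counts$n[counts$label != "outside"])
    reports$clusters <- c(meta, list(
      window = list(start = win$window_start, width = win$width,
                    count = win$count,
                    forward = sum(tc$orientation[win$members] == "TCF3::PBX1"),
                    pct = percent(win$count, nrow(tc))),
      pbx1_regions = counts,
      pbx1_combined_pct = percent(in_regions, nrow(pb))))
    write.table(counts, file.path(run_dir, "pbx1_region_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("overlap" %in% stages) {
    if (is.null(config$tracks))
      stop("stage 'overlap' needs config$tracks", call. = FALSE)
    res <- lapply(names(config$tracks), function(nm) {
      trk <- read_track(config$tracks[[nm]])
      pb <- breakpoints(cat49, gene = "PBX1")
      ov <- fraction_overlapping(pb$position, trk, vicinity = config$vicinity)
      c(list(track = nm), ov)
    })
    reports$overlap <- c(meta, list(tracks = res))
  }

  if ("qpcr" %in% stages) {
    tab <- read.csv(config$qpcr_curves, comment.char = "#",
                    stringsAsFactors = FALSE)
    tab$efficiency_recomputed <- round(efficiency_from_slope(tab$slope), 3)
    reports$qpcr <- c(meta, list(curves = tab))
    write.table(tab, file.path(run_dir, "qpcr_curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if ("simulate" %in% stages) {
    n <- config$simulate$n %||% 100L
    sim <- simulate_cohort(
      n, seed = config$seed,
      fasta_path = file.path(run_dir, "simulated_derivatives.fa"),
      truth_path = file.path(run_dir, "simulated_truth.tsv"))
    reports$simulate <- c(meta, list(
      n = n, n_sequences = length(sim$derivatives),
      occupancy = as.list(table(sim$truth$pbx1_component))))
  }

  for (nm in names(reports))
    jsonlite::write_json(reports[[nm]],
                         file.path(run_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  attr(reports, "run_dir") <- run_dir
  invisible(reports)
}
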