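.CATALOG_COLS <- c("patient_id", "sex", "age", "phenotype", "sample_type",
                   "gene", "orientation", "position", "accession", "note")

#' Load a breakpoint catalog
#'
#' Reads a long-format TSV with one row per break event (columns
#' `patient_id, sex, age, phenotype, sample_type, gene, orientation,
#' position, accession, note`; `#` lines are comments) and validates it:
#' closed vocabularies for sex/phenotype/sample type/gene/orientation,
#' non-negative integer ages, and intron-relative positions within the
#' host intron (TCF3 intron 16: 3289 bp; PBX1 intron 2: 229,182 bp).
#' Nothing is dropped silently; any violation is an error naming the row.
#'
#' @param path path to the TSV file. Defaults to the packaged catalog of 49
#'   adult t(1;19) patients (64 TCF3-side and 65 PBX1-side break events).
#' @return an object of class `breakpoint_catalog`: a list with elements
#'   `patients` (one row per patient) and `breaks` (one row per break event).
#' @examples
#' cat49 <- load_catalog()
#' nrow(cat49$patients)                      # 49
#' table(cat49$breaks$gene)                  # TCF3 64, PBX1 65
#' @export
load_catalog <- function(path = fusionbreak_example("breakpoint_catalog.tsv")) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse catalog: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0L || !all(.CATALOG_COLS %in% names(df)))
    stop("catalog schema error: expected columns ",
         paste(.CATALOG_COLS, collapse = ", "), call. = FALSE)
  df <- df[.CATALOG_COLS]
  df$age <- suppressWarnings(as.integer(df$age))
  df$position <- suppressWarnings(as.integer(df$position))

  .vocab <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad))
      stop(sprintf("catalog validation error: row %d has %s '%s' (allowed: %s)",
                   bad[1L], col, df[[col]][bad[1L]],
                   paste(allowed, collapse = "/")), call. = FALSE)
  }
  .vocab("sex", c("f", "m"))
  .vocab("phenotype", c("pre-B", "common"))
  .vocab("sample_type", c("bm", "pb", "unknown"))
  .vocab("gene", c("TCF3", "PBX1"))
  .vocab("orientation", c("TCF3::PBX1", "PBX1::TCF3"))
  if (anyNA(df$age) || any(df$age < 0L))
    stop("catalog validation error: row ",
         which(is.na(df$age) | df$age < 0L)[1L], " has invalid age",
         call. = FALSE)

  lens <- c(TCF3 = tcf3_intron16()$length, PBX1 = pbx1_intron2()$length)
  bad <- which(is.na(df$position) | df$position < 1L |
               df$position > lens[df$gene])
  if (length(bad))
    stop(sprintf(paste0("catalog validation error: row %d (%s) position %s ",
                        "outside 1..%d of %s intron"),
                 bad[1L], df$patient_id[bad[1L]], df$position[bad[1L]],
                 lens[df$gene[bad[1L]]], df$gene[bad[1L]]), call. = FALSE)

  pat <- df[!duplicated(df$patient_id),
            c("patient_id", "sex", "age", "phenotype", "sample_type",
              "accession")]
  rownames(pat) <- rownames(df) <- NULL
  structure(list(patients = pat, breaks = df, source = path),
            class = "breakpoint_catalog")
}

#' @export
print.breakpoint_catalog <- function(x, ...) {
  cat(sprintf("<breakpoint_catalog> %d patients, %d break events (%d TCF3-side, %d PBX1-side)\n",
              nrow(x$patients), nrow(x$breaks),
              sum(x$breaks$gene == "TCF3"), sum(x$breaks$gene == "PBX1")))
  invisible(x)
}

#' Extract break events from a catalog
#'
#' @param catalog a `breakpoint_catalog`.
#' @param gene optional filter, `"TCF3"` or `"PBX1"`.
#' @param orientation optional filter, `"TCF3::PBX1"` or `"PBX1::TCF3"`.
#' @return data.frame of break events.
#' @export
breakpoints <- function(catalog, gene = NULL, orientation = NULL) {
  stopifnot(inherits(catalog, "breakpoint_catalog"))
  b <- catalog$breaks
  if (!is.null(gene)) b <- b[b$gene == gene, ]
  if (!is.null(orientation)) b <- b[b$orientation == orientation, ]
  rownames(b) <- NULL
  b
}

#' Summarize a breakpoint catalog
#'
#' Cohort counts by sex, phenotype, sample type, and per-gene break counts by
#' orientation, plus age median (midpoint convention for even counts, i.e.
#' [stats::median()]) and range.
#'
#' @param catalog a `breakpoint_catalog`.
#' @return a list of class `catalog_summary`.
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "breakpoint_catalog"))
  p <- catalog$patients
  b <- catalog$breaks
  if (nrow(p) == 0L) stop("empty catalog", call. = FALSE)
  structure(list(
    n_patients = nrow(p),
    sex = c(f = sum(p$sex == "f"), m = sum(p$sex == "m")),
    phenotype = c(`pre-B` = sum(p$phenotype == "pre-B"),
                  common = sum(p$phenotype == "common")),
    sample_type = c(bm = sum(p$sample_type == "bm"),
                    pb = sum(p$sample_type == "pb"),
                    unknown = sum(p$sample_type == "unknown")),
    age = list(median = median(p$age), min = min(p$age), max = max(p$age)),
    breaks = as.matrix(table(gene = b$gene, orientation = b$orientation))
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d f / %d m); phenotype pre-B %d, common %d\n",
              x$n_patients, x$sex["f"], x$sex["m"],
              x$phenotype["pre-B"], x$phenotype["common"]))
  cat(sprintf("Sample: bm %d, pb %d, unknown %d; age median %.1f (range %d-%d)\n",
              x$sample_type["bm"], x$sample_type["pb"], x$sample_type["unknown"],
              x$age$median, x$age$min, x$age$max))
  cat("Break events by gene x orientation:\n")
  print(x$breaks)
  invisible(x)
}

#' Export genomic-converted breakpoints as BED
#'
#' Converts intron-relative breakpoints to genomic coordinates (see
#' [intron_to_genomic()]) and writes a 0-based half-open BED file whose
#' `track` header line records the anchoring mode.
#'
#' @param catalog a `breakpoint_catalog`.
#' @param path output file.
#' @param mode anchoring mode passed to [intron_to_genomic()].
#' @return `path`, invisibly.
#' @export
write_breakpoints_bed <- function(catalog, path,
                                  mode = c("plus-anchored", "minus-anchored")) {
  stopifnot(inherits(catalog, "breakpoint_catalog"))
  mode <- match.arg(mode)
  spaces <- list(TCF3 = tcf3_intron16(), PBX1 = pbx1_intron2())
  b <- catalog$breaks
  g <- vapply(seq_len(nrow(b)), function(i)
    intron_to_genomic(spaces[[b$gene[i]]], b$position[i], mode)$genomic,
    integer(1))
  chrom <- vapply(b$gene, function(x) spaces[[x]]$chrom, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="fusionbreak_breakpoints" description="anchoring=%s"',
                     mode), con)
  write.table(
    data.frame(chrom, g - 1L, g, paste(b$patient_id, b$gene, b$orientation,
                                       sep = "|")),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under the package's `extdata`; empty lists them.
#' @return file path.
#' @export
fusionbreak_example <- function(file = "") {
  if (nzchar(file)) system.file("extdata", file, package = "fusionbreak",
                                mustWork = TRUE)
  else dir(system.file("extdata", package = "fusionbreak"))
}
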