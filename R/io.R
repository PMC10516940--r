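## File formats and run reports. All tables are tab-separated UTF-8 with '#'
## comment lines; genotype panels additionally load from VCF (1-based,
## biallelic SNVs only); reports are JSON with deterministic key order,
## validated against the schema shipped under inst/schema/.

#' Read a per-cell score table
#'
#' Expects tab-separated columns `cell_id`, `true_label`, one `score_<class>`
#' column per output class, and optionally `arrival_time` (seconds). Score
#' rows must lie on the simplex: deviations of the row sum from 1 up to 1e-6
#' are accepted as-is, up to 1e-3 are renormalised with a warning, and larger
#' deviations reject the file.
#'
#' @param path Path to the TSV file.
#' @return A [CellCohort-class] in file order.
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  required <- c("cell_id", "true_label")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  scoreCols <- grep("^score_", names(df), value = TRUE)
  if (length(scoreCols) < 2L) {
    stop("at least two score_<class> columns are required")
  }
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup)) {
    stop("duplicate cell_id: ", paste(unique(dup), collapse = ", "))
  }
  scores <- as.matrix(df[, scoreCols, drop = FALSE])
  if (!is.numeric(scores)) stop("score columns must be numeric")
  storage.mode(scores) <- "double"
  colnames(scores) <- sub("^score_", "", scoreCols)
  if (nrow(scores) > 0) {
    dev <- abs(rowSums(scores) - 1)
    if (any(dev > 1e-3)) {
      stop(sprintf("score rows deviate from the simplex by up to %.3g (> 1e-3)",
                   max(dev)))
    }
    renorm <- dev > 1e-6
    if (any(renorm)) {
      warning(sprintf("renormalised %d score row(s) with |sum - 1| in (1e-6, 1e-3]",
                      sum(renorm)))
      scores[renorm, ] <- scores[renorm, , drop = FALSE] /
        rowSums(scores[renorm, , drop = FALSE])
    }
  }
  CellCohort(cellId = as.character(df$cell_id),
             trueLabel = as.character(df$true_label), scores = scores,
             arrivalTime = if ("arrival_time" %in% names(df)) {
               as.numeric(df$arrival_time)
             } else NULL)
}

#' Write a cohort to the per-cell score table format
#'
#' @param cohort A [CellCohort-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCellTable <- function(cohort, path) {
  stopifnot(is(cohort, "CellCohort"))
  s <- scoreMatrix(cohort)
  df <- data.frame(cell_id = cellIds(cohort), true_label = trueLabels(cohort),
                   stringsAsFactors = FALSE)
  sdf <- as.data.frame(s)
  names(sdf) <- paste0("score_", colnames(s))
  df <- cbind(df, sdf)
  if (!is.null(arrivalTimes(cohort))) df$arrival_time <- arrivalTimes(cohort)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an embedding matrix as TSV
#'
#' @param embeddings n x d matrix.
#' @param path Output path; a `# n d` comment header records the shape.
#' @return Invisibly, the path.
#' @export
writeEmbeddingTable <- function(embeddings, path) {
  embeddings <- as.matrix(embeddings)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d", nrow(embeddings), ncol(embeddings)), con)
  write.table(embeddings, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by [writeEmbeddingTable()]
#' @param path Path to the TSV file.
#' @return Numeric matrix.
#' @export
readEmbeddingTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as.matrix(read.delim(path, comment.char = "#", header = FALSE))
}

## Internal: map diploid GT strings to dosages; NA for anything else.
gtToDosage <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  ifelse(gt %in% c("0/0"), 0,
         ifelse(gt %in% c("0/1", "1/0"), 0.5,
                ifelse(gt %in% c("1/1"), 1, NA_real_)))
}

#' Read a genotype panel from VCF or TSV
#'
#' VCF input keeps biallelic SNVs only; multi-allelic and indel records are
#' skipped and counted on the returned panel, as are records with missing or
#' non-diploid genotypes in either sample. GT fields 0/0, 0/1, 1/1 map to
#' dosages 0, 0.5, 1; positions are 1-based. TSV input needs columns
#' `variant_id`, `g_target`, `g_background`.
#'
#' @param path Path to a `.vcf` or panel `.tsv` file.
#' @param targetSample,backgroundSample Sample column names (VCF only).
#' @return A [GenotypePanel-class].
#' @export
readGenotypePanel <- function(path, targetSample = NULL,
                              backgroundSample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (is.null(targetSample) || is.null(backgroundSample)) {
      stop("VCF input needs 'targetSample' and 'backgroundSample'")
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    have <- colnames(gt)
    for (s in c(targetSample, backgroundSample)) {
      if (!s %in% have) {
        stop(sprintf("sample '%s' not present in VCF (has: %s)", s,
                     paste(have, collapse = ", ")))
      }
    }
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
      !grepl(",", alt)
    dT <- gtToDosage(gt[, targetSample])
    dB <- gtToDosage(gt[, backgroundSample])
    ok <- snv & !is.na(dT) & !is.na(dB)
    nSkipped <- sum(!ok)
    if (nSkipped > 0) {
      warning(sprintf("skipped %d record(s): multi-allelic, non-SNV or missing GT",
                      nSkipped))
    }
    id <- fix[, "ID"]
    id <- ifelse(is.na(id) | id == ".",
                 paste0(fix[, "CHROM"], ":", fix[, "POS"]), id)
    GenotypePanel(variantId = id[ok], gTarget = dT[ok], gBackground = dB[ok],
                  chrom = fix[ok, "CHROM"], pos = as.integer(fix[ok, "POS"]),
                  ref = ref[ok], alt = alt[ok], nSkipped = nSkipped)
  } else {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("variant_id", "g_target", "g_background")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("panel TSV missing column(s): ", paste(missing, collapse = ", "))
    }
    GenotypePanel(variantId = df$variant_id, gTarget = df$g_target,
                  gBackground = df$g_background)
  }
}

#' Read per-variant allele counts from TSV
#'
#' Needs columns `variant_id`, `ref_count`, `alt_count`.
#'
#' @param path Path to the TSV file.
#' @return An [AlleleCounts-class].
#' @export
readAlleleCounts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("variant_id", "ref_count", "alt_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("counts TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  AlleleCounts(df$variant_id, df$ref_count, df$alt_count)
}

#' Write ROC or PR curves as TSV
#'
#' @param curve A [ROCCurve-class] or [PRCurve-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCurveTable <- function(curve, path) {
  df <- if (is(curve, "ROCCurve")) {
    data.frame(threshold = curve@thresholds, tpr = curve@tpr, fpr = curve@fpr)
  } else if (is(curve, "PRCurve")) {
    data.frame(threshold = curve@thresholds, recall = curve@recall,
               precision = curve@precision, fpr = curve@fpr)
  } else {
    stop("'curve' must be a ROCCurve or PRCurve")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value run configuration
#'
#' Lines are `key = value`; '#' starts a comment. When `allowedKeys` is
#' given, unknown keys reject the file.
#'
#' @param path Path to the config file.
#' @param allowedKeys Optional character vector of permitted keys.
#' @return Named list of string values.
#' @export
readRunConfig <- function(path, allowedKeys = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  if (anyDuplicated(keys)) stop("duplicate config key: ",
                                keys[duplicated(keys)][1])
  if (!is.null(allowedKeys)) {
    unknown <- setdiff(keys, allowedKeys)
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
  }
  setNames(as.list(vals), keys)
}

#' Write a flat key=value run configuration
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, "")), path)
  invisible(path)
}

REPORT_FORMAT_VERSION <- "1.0"

#' Assemble a run report
#'
#' @param config Named list echoing the run configuration (must include a
#'   `seed`).
#' @param results Named list of per-module outputs (sort summaries, purity
#'   estimates, curve summaries, ...).
#' @param created Timestamp string; fixed at creation so identical reports
#'   serialise byte-identically.
#' @return A `runReport` list, schema-valid for [writeReport()].
#' @export
makeRunReport <- function(config, results,
                          created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  report <- list(
    format_version = REPORT_FORMAT_VERSION,
    tool = "icasort",
    tool_version = as.character(packageVersion("icasort")),
    created = created,
    config = config,
    results = results)
  class(report) <- c("runReport", "list")
  report
}

#' Validate a run report against the shipped schema
#'
#' @param report A report list.
#' @return TRUE invisibly; otherwise an error naming the violation.
#' @export
validateRunReport <- function(report) {
  schemaPath <- system.file("schema", "run-report.json", package = "icasort")
  schema <- jsonlite::fromJSON(schemaPath, simplifyVector = TRUE)
  for (key in schema$required) {
    if (is.null(report[[key]])) stop("report is missing required key: ", key)
  }
  types <- schema$properties
  for (key in names(types)) {
    if (is.null(report[[key]])) next
    want <- types[[key]]$type
    ok <- switch(want,
                 string = is.character(report[[key]]) &&
                   length(report[[key]]) == 1L,
                 object = is.list(report[[key]]),
                 TRUE)
    if (!ok) stop(sprintf("report key '%s' must be a JSON %s", key, want))
  }
  if (is.null(report$config$seed)) stop("report config must record a seed")
  invisible(TRUE)
}

#' Write a run report as deterministic JSON
#'
#' Keys are emitted in fixed order; identical reports produce byte-identical
#' files. The report is schema-validated before anything is written.
#'
#' @param report A report from [makeRunReport()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeReport <- function(report, path) {
  validateRunReport(report)
  ordered <- report[c("format_version", "tool", "tool_version", "created",
                      "config", "results")]
  json <- jsonlite::toJSON(ordered, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a run report written by [writeReport()]
#' @param path Path to the JSON file.
#' @return The report list.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  report <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  class(report) <- c("runReport", "list")
  report
}

#' Persist an annotation session as TSV plus JSON sidecar
#'
#' @param session An [AnnotationSession-class].
#' @param path Path of the session TSV; the sidecar (taxonomy, constraints,
#'   metadata) is written next to it with extension `.json`.
#' @return Invisibly, the TSV path.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "AnnotationSession"))
  df <- data.frame(cell_id = session@cellIds, cluster = session@clusters,
                   label = session@labels, provenance = session@provenance,
                   labeler = session@labeler, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  sidecar <- list(
    taxonomy = list(labels = session@taxonomy@labels,
                    parent = as.list(session@taxonomy@parent)),
    constraints = lapply(session@constraints, function(con) {
      list(when = con@when, disallow = con@disallow)
    }),
    metadata = session@metadata)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", na = "null"),
             sub("\\.tsv$", ".json", path))
  invisible(path)
}
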