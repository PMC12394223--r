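# TSV + JSON interchange formats. All matrices are UTF-8 TSV with a
# header row; the leading column(s) carry identifiers, the remaining
# columns are decimals serialized with 17 significant digits so that
# read(write(x)) round-trips doubles exactly.

fmt_num <- function(x) sprintf("%.17g", x)

matrix_meta_cols <- function(role) {
  switch(role,
    embedding = "sample_id",
    logits    = "sample_id",
    text      = "class_name",
    bank      = c("sample_id", "class"),
    ke_parameter_error(sprintf("unknown matrix role '%s'", role)))
}

#' Write a typed matrix to TSV
#'
#' Serializes a [logit_matrix()], [embedding_matrix()],
#' [text_embeddings()] or [feature_bank()] to a tab-separated file with
#' a header row. Identifier columns come first (`sample_id`, plus
#' `class` for banks; `class_name` for text embeddings), followed by the
#' numeric columns at 17 significant digits (lossless for doubles).
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "ke_bank")) {
    vals <- x$embeddings$values
    header <- c("sample_id", "class", colnames(vals) %||%
                  paste0("d", seq_len(ncol(vals))))
    body <- paste(x$embeddings$sample_ids, x$classes,
                  apply(vals, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
                  sep = "\t")
  } else if (inherits(x, "ke_logits")) {
    header <- c("sample_id", x$class_names)
    body <- paste(x$sample_ids,
                  apply(x$values, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
                  sep = "\t")
  } else if (inherits(x, "ke_embed")) {
    header <- c("sample_id", colnames(x$values) %||%
                  paste0("d", seq_len(ncol(x$values))))
    body <- paste(x$sample_ids,
                  apply(x$values, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
                  sep = "\t")
  } else if (inherits(x, "ke_text")) {
    header <- c("class_name", paste0("d", seq_len(ncol(x$values))))
    body <- paste(x$class_names,
                  apply(x$values, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
                  sep = "\t")
  } else {
    ke_input_error("write_matrix() accepts ke_logits, ke_embed, ke_text or ke_bank")
  }
  writeLines(c(paste(header, collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}

# Shared TSV reader with line-numbered errors (header is line 1).
read_tsv_checked <- function(path, n_meta) {
  if (!file.exists(path)) ke_input_error(sprintf("file not found: %s", path))
  nfields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  ragged <- which(nfields != nfields[1L])
  if (length(ragged) > 0L)
    ke_parse_error(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                           path, ragged[1L], nfields[ragged[1L]], nfields[1L]))
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = "character", fill = FALSE,
                      data.table = FALSE, showProgress = FALSE),
    error = function(e) ke_parse_error(
      sprintf("malformed TSV %s: %s", path, conditionMessage(e))))
  if (ncol(dt) <= n_meta)
    ke_parse_error(sprintf("%s: no numeric columns after %d id column(s)",
                           path, n_meta))
  ids <- dt[[1L]]
  dup <- which(duplicated(ids))
  if (length(dup) > 0L)
    ke_parse_error(sprintf("%s: duplicate id '%s' at line %d",
                           path, ids[dup[1L]], dup[1L] + 1L))
  num <- as.matrix(dt[, -seq_len(n_meta), drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  bad <- which(!is.finite(num) & dt[, -seq_len(n_meta)] != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    ke_parse_error(sprintf("%s: non-numeric cell in column '%s' at line %d",
                           path, colnames(num)[bad[1L, 2L]], bad[1L, 1L] + 1L))
  if (anyNA(num))
    ke_parse_error(sprintf("%s: missing values are not allowed", path))
  list(meta = dt[, seq_len(n_meta), drop = FALSE], values = num,
       colnames = colnames(dt)[-seq_len(n_meta)])
}

#' Read a typed matrix from TSV
#'
#' Counterpart of [write_matrix()]. The `role` selects the returned
#' type; embeddings and banks additionally need the model-space tag.
#' Malformed input (ragged rows, non-numeric cells, duplicate ids) is
#' rejected with the offending line named; a declared dimension that
#' does not match the file is an error.
#'
#' @param path TSV file path.
#' @param role `"embedding"`, `"logits"`, `"text"` or `"bank"`.
#' @param space_tag `"finetuned"` or `"pretrained"` (embedding/bank
#'   roles).
#' @param expected_dim optional number of numeric columns to enforce
#'   (from a manifest).
#' @return A [embedding_matrix()], [logit_matrix()], [text_embeddings()]
#'   or [feature_bank()].
#' @export
read_matrix <- function(path, role = c("embedding", "logits", "text", "bank"),
                        space_tag = NULL, expected_dim = NULL) {
  role <- match.arg(role)
  n_meta <- length(matrix_meta_cols(role))
  parsed <- read_tsv_checked(path, n_meta)
  if (!is.null(expected_dim) && ncol(parsed$values) != expected_dim)
    ke_parse_error(sprintf(
      "%s: manifest declares %d numeric columns but file has %d",
      path, expected_dim, ncol(parsed$values)))
  switch(role,
    embedding = embedding_matrix(parsed$values,
                                 space_tag = space_tag %||% "finetuned",
                                 sample_ids = parsed$meta[[1L]]),
    logits = logit_matrix(parsed$values, sample_ids = parsed$meta[[1L]],
                          class_names = parsed$colnames),
    text = text_embeddings(parsed$values, class_names = parsed$meta[[1L]]),
    bank = feature_bank(
      embedding_matrix(parsed$values, space_tag = space_tag %||% "finetuned",
                       sample_ids = parsed$meta[[1L]]),
      parsed$meta[[2L]]))
}

#' Write / read the per-sample labels file
#'
#' TSV with columns `sample_id`, `membership` (`known`/`unknown`) and
#' `class`.
#'
#' @param truth a [ground_truth()].
#' @param path file path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()`
#'   returns a [ground_truth()].
#' @export
write_labels <- function(truth, path) {
  if (!inherits(truth, "ke_truth"))
    ke_input_error("'truth' must be a ground_truth()")
  writeLines(c("sample_id\tmembership\tclass",
               paste(truth$sample_ids, truth$membership, truth$class_label,
                     sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) ke_input_error(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          showProgress = FALSE)
  need <- c("sample_id", "membership", "class")
  if (!all(need %in% colnames(dt)))
    ke_parse_error(sprintf("%s: labels file must have columns %s",
                           path, paste(need, collapse = ", ")))
  ground_truth(dt$sample_id, dt$membership, dt$class)
}

MANIFEST_VERSION <- "1.0"

#' Write a fixture directory with its JSON manifest
#'
#' Serializes a complete bundle (banks, test embeddings, logits, text
#' embeddings, labels) as TSV files plus a `manifest.json` describing
#' every file's role, the model spaces, the ensemble defaults and the
#' seed provenance. The directory round-trips through [read_fixture()].
#'
#' @param bundle a `ke_bundle` (see [generate_bundle()]).
#' @param dir output directory (created if missing).
#' @param mode default ensemble mode recorded in the manifest.
#' @param base_cpd_method default CPD base recorded in the manifest.
#' @param temperature,tpr_level defaults recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(bundle, dir, mode = "visual_three_way",
                          base_cpd_method = NULL, temperature = 1,
                          tpr_level = 0.95) {
  if (!inherits(bundle, "ke_bundle"))
    ke_input_error("'bundle' must be a ke_bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(bank_ft = "bank_ft.tsv", bank_pt = "bank_pt.tsv",
                test_ft = "test_ft.tsv", test_pt = "test_pt.tsv",
                logits = "logits.tsv", text = "text.tsv",
                labels = "labels.tsv")
  write_matrix(bundle$bank_ft, file.path(dir, files$bank_ft))
  write_matrix(bundle$bank_pt, file.path(dir, files$bank_pt))
  write_matrix(bundle$test_feats_ft, file.path(dir, files$test_ft))
  write_matrix(bundle$test_feats_pt, file.path(dir, files$test_pt))
  write_matrix(bundle$test_logits, file.path(dir, files$logits))
  write_matrix(bundle$text_feats, file.path(dir, files$text))
  write_labels(bundle$truth, file.path(dir, files$labels))
  d <- ncol(bundle$test_feats_ft$values)
  manifest <- list(
    format_version = MANIFEST_VERSION,
    seed = bundle$config$seed,
    ensemble = list(mode = mode,
                    base_cpd_method = base_cpd_method %||%
                      ensemble_spec(mode)$base_cpd_method),
    temperature = temperature,
    tpr_level = tpr_level,
    spaces = list(
      finetuned = list(model = "finetuned-encoder", d = d,
                       l2_normalized = TRUE),
      pretrained = list(model = "pretrained-encoder", d = d,
                        l2_normalized = TRUE)),
    files = files,
    generator = unclass(bundle$config)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and validate a fixture manifest
#'
#' Checks the format version and that every referenced file exists.
#'
#' @param path path to `manifest.json` (or to the fixture directory).
#' @return The manifest as a list, with the fixture directory attached
#'   as attribute `"dir"`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path))
    ke_input_error(sprintf("manifest not found: %s", path))
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(manifest$format_version) ||
      !manifest$format_version %in% MANIFEST_VERSION)
    ke_parse_error(sprintf("unrecognized manifest format_version '%s'",
                           manifest$format_version %||% "<missing>"))
  dir <- dirname(path)
  for (role in names(manifest$files)) {
    f <- file.path(dir, manifest$files[[role]])
    if (!file.exists(f))
      ke_input_error(sprintf("manifest references missing file for role '%s': %s",
                             role, f))
  }
  attr(manifest, "dir") <- dir
  manifest
}

#' Load a fixture directory back into pipeline inputs
#'
#' Reads every file referenced by the manifest and reconstructs the
#' typed objects, validating declared dimensions along the way. The
#' result has the same shape as a [generate_bundle()] output (minus the
#' generator config) and can be passed to [run_bundle()].
#'
#' @param path fixture directory or manifest path.
#' @return A `ke_bundle`-classed list.
#' @export
read_fixture <- function(path) {
  manifest <- read_manifest(path)
  dir <- attr(manifest, "dir")
  fp <- function(role) file.path(dir, manifest$files[[role]])
  d_ft <- manifest$spaces$finetuned$d
  d_pt <- manifest$spaces$pretrained$d
  truth <- read_labels(fp("labels"))
  bundle <- list(
    bank_ft = read_matrix(fp("bank_ft"), "bank", "finetuned", d_ft),
    bank_pt = read_matrix(fp("bank_pt"), "bank", "pretrained", d_pt),
    test_feats_ft = read_matrix(fp("test_ft"), "embedding", "finetuned", d_ft),
    test_feats_pt = read_matrix(fp("test_pt"), "embedding", "pretrained", d_pt),
    test_logits = read_matrix(fp("logits"), "logits"),
    text_feats = read_matrix(fp("text"), "text"),
    truth = truth,
    split = validate_split(split_from_truth(truth)),
    manifest = manifest
  )
  class(bundle) <- "ke_bundle"
  bundle
}

#' Write per-sample scores to TSV
#'
#' Columns: `sample_id`, `membership`, then one column per score kind.
#'
#' @param scores named list of [score_vector()]s sharing ids and order.
#' @param truth a [ground_truth()] with matching ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, truth, path) {
  if (!is.list(scores) || length(scores) == 0L || is.null(names(scores)))
    ke_input_error("'scores' must be a named list of score vectors")
  ids <- names(scores[[1L]])
  for (s in scores) {
    if (!identical(names(s), ids))
      ke_alignment_error("score vectors disagree on sample ids")
  }
  if (!identical(truth$sample_ids, ids))
    ke_alignment_error("scores and ground truth disagree on sample ids")
  header <- c("sample_id", "membership", names(scores))
  cols <- vapply(scores, function(s) fmt_num(as.numeric(s)),
                 character(length(ids)))
  if (length(ids) == 1L) cols <- matrix(cols, nrow = 1L)
  body <- paste(ids, truth$membership,
                apply(cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(paste(header, collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}

#' Write a metrics report as flat JSON
#'
#' @param metrics a `ke_metrics` object ([evaluate_scores()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(metrics, path) {
  if (!inherits(metrics, "ke_metrics"))
    ke_input_error("'metrics' must be a ke_metrics object")
  jsonlite::write_json(metrics_as_list(metrics), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a score-distribution histogram table to TSV
#'
#' @param histogram a data.frame from [export_score_distributions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(histogram, path) {
  lines <- c(paste(colnames(histogram), collapse = "\t"),
             apply(histogram, 1L, function(r) paste(
               c(r[["bin"]], fmt_num(as.numeric(r[["lower"]])),
                 fmt_num(as.numeric(r[["upper"]])), r[["known"]],
                 r[["unknown"]]), collapse = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
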