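#' @keywords internal
"_PACKAGE"

# Delimiter from file extension; header row is mandatory in all matrix formats.
.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.norm_id <- function(x, normalize = FALSE) {
  if (normalize) toupper(trimws(x)) else x
}

#' Expression matrix for one profiling platform
#'
#' Container for log2 intensities (or raw linear signals, for protein panels
#' ahead of normalisation) of one platform: features in rows, samples in
#' columns. An optional logical `detection` matrix of the same shape records
#' per-cell expressed/not-expressed calls.
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param platform one of `"mRNA"`, `"miRNA"`, `"protein"`.
#' @param detection optional logical matrix, same dimnames as `values`.
#' @param unit free-text declaration of the measurement unit.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, platform = c("mRNA", "miRNA", "protein"),
                              detection = NULL, unit = "log2 intensity") {
  platform <- match.arg(platform)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!is.null(detection)) {
    stopifnot(is.logical(detection), identical(dim(detection), dim(values)))
    dimnames(detection) <- dimnames(values)
  }
  structure(list(platform = platform, values = values,
                 detection = detection, unit = unit),
            class = "expression_matrix")
}

#' Log2 fold-change matrix
#'
#' Treated samples only; each cell is the log2 ratio of a treated sample
#' against its time-matched vehicle control group. Missing cells are `NA`.
#'
#' @param log_ratios numeric matrix, features x treated samples, dimnames set.
#' @param platform one of `"mRNA"`, `"miRNA"`, `"protein"`.
#' @return an object of class `fold_change_matrix`.
#' @export
fold_change_matrix <- function(log_ratios, platform = c("mRNA", "miRNA", "protein")) {
  platform <- match.arg(platform)
  stopifnot(is.matrix(log_ratios), is.numeric(log_ratios))
  if (is.null(rownames(log_ratios)) || is.null(colnames(log_ratios)))
    stop("fold-change matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(log_ratios)))
    stop("duplicated feature ids in fold-change matrix")
  bad <- is.infinite(log_ratios)
  if (any(bad)) stop("non-finite (infinite) log-ratios present")
  structure(list(platform = platform, log_ratios = log_ratios),
            class = "fold_change_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d features x %d samples (%s)%s\n",
              x$platform, nrow(x$values), ncol(x$values), x$unit,
              if (is.null(x$detection)) "" else ", with detection flags"))
  invisible(x)
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf("<fold_change_matrix> %s: %d features x %d samples, %d missing cells\n",
              x$platform, nrow(x$log_ratios), ncol(x$log_ratios),
              sum(is.na(x$log_ratios))))
  invisible(x)
}

# Strict delimited-matrix parser: header mandatory, ragged rows and duplicate
# feature ids are errors, empty cells become NA (missing, never zero).
.read_matrix_file <- function(path, delim = .delim_for(path)) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty file: ", path)
  # sentinel keeps trailing empty cells, which strsplit would drop
  fields <- lapply(strsplit(paste0(lines, delim, "\x01"), delim, fixed = TRUE),
                   function(f) f[-length(f)])
  header <- fields[[1L]]
  samples <- header[-1L]
  ncol_expected <- length(header)
  vals <- matrix(NA_real_, nrow = length(fields) - 1L, ncol = length(samples))
  ids <- character(nrow(vals))
  for (i in seq_len(length(fields) - 1L)) {
    row <- fields[[i + 1L]]
    if (length(row) != ncol_expected)
      stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                   i + 1L, ncol_expected, length(row)))
    ids[i] <- row[1L]
    cells <- row[-1L]
    cells[cells == "" | cells == "NA"] <- NA
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at line %d, column %d (sample %s)",
                   cells[bad[1L]], i + 1L, bad[1L] + 1L, samples[bad[1L]]))
    vals[i, ] <- num
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Read an expression matrix from TSV/CSV
#'
#' First column holds feature ids, header row holds sample ids. Empty cells
#' are read as missing values, never as zero.
#'
#' @param path file path (`.csv` comma-delimited, otherwise tab).
#' @param platform platform tag for the matrix.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, platform, unit = "log2 intensity") {
  expression_matrix(.read_matrix_file(path), platform = platform, unit = unit)
}

#' Read a fold-change matrix from TSV/CSV
#' @param path file path.
#' @param platform platform tag.
#' @return a [fold_change_matrix()].
#' @export
read_fold_changes <- function(path, platform) {
  fold_change_matrix(.read_matrix_file(path), platform = platform)
}

#' Write a fold-change matrix (12 significant digits, round-trip safe)
#' @param fc a [fold_change_matrix()].
#' @param path output path (`.csv` comma-delimited, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fc, path) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  delim <- .delim_for(path)
  m <- fc$log_ratios
  body <- apply(m, 1L, function(r) {
    s <- formatC(r, digits = 12, format = "g")
    s[is.na(r)] <- ""
    paste(s, collapse = delim)
  })
  lines <- c(paste(c("feature_id", colnames(m)), collapse = delim),
             paste(rownames(m), body, sep = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Expects columns `sample_id`, `compound`, `class_label`, `dosing_time`,
#' `vehicle`, `is_control`, `control_group_id`. Class labels must be one of
#' GC, NGC, NC, UNDEFINED (controls may carry any label; it is ignored).
#'
#' @param path TSV/CSV path.
#' @return a `data.frame` of class `sample_annotation`.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  as_sample_annotation(df)
}

#' Validate a sample annotation data frame
#' @param df data frame with the annotation columns.
#' @return `df` with class `sample_annotation` prepended.
#' @export
as_sample_annotation <- function(df) {
  need <- c("sample_id", "compound", "class_label", "is_control", "control_group_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  df$is_control <- as.logical(df$is_control)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in annotation")
  treated <- df[!df$is_control, , drop = FALSE]
  bad <- setdiff(treated$class_label, c("GC", "NGC", "NC", "UNDEFINED"))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  cls_per_cmp <- tapply(treated$class_label, treated$compound,
                        function(x) length(unique(x)))
  if (any(cls_per_cmp > 1L))
    stop("compound(s) mapped to more than one class: ",
         paste(names(cls_per_cmp)[cls_per_cmp > 1L], collapse = ", "))
  class(df) <- c("sample_annotation", class(df))
  df
}

#' Read a gene-set collection in GMT format
#'
#' One pathway per line: id, description, then gene ids, tab-separated.
#' Duplicate genes within a line are collapsed. The universe (union of all
#' sets) is cached on the result.
#'
#' @param path GMT file path.
#' @param source database tag attached to every set (`"KEGG"`, `"Reactome"`,
#'   `"BioCarta"` or `"custom"`).
#' @return a `pathway_collection`: list with `sets` (named list of gene-id
#'   vectors), `source`, `name` and cached `universe`.
#' @export
read_gmt <- function(path, source = c("custom", "KEGG", "Reactome", "BioCarta")) {
  source <- match.arg(source)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1L]))
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicated pathway id in GMT: ",
                               ids[duplicated(ids)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  if (any(lengths(sets) == 0L)) stop("empty gene set in GMT")
  pathway_collection(sets,
                     name = stats::setNames(vapply(fields, `[`, "", 2L), ids),
                     source = stats::setNames(rep(source, length(ids)), ids))
}

#' Construct a pathway collection
#' @param sets named list of non-empty gene-id character vectors.
#' @param name optional named display names.
#' @param source named database tags per set.
#' @return a `pathway_collection`.
#' @export
pathway_collection <- function(sets, name = NULL,
                               source = stats::setNames(rep("custom", length(sets)),
                                                        names(sets))) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(lengths(sets) > 0L))
  sets <- lapply(sets, unique)
  structure(list(sets = sets,
                 name = if (is.null(name)) stats::setNames(names(sets), names(sets)) else name,
                 source = source,
                 universe = unique(unlist(sets, use.names = FALSE))),
            class = "pathway_collection")
}

#' Combine pathway collections from several databases into one
#' @param ... `pathway_collection` objects.
#' @return a pooled `pathway_collection` with one shared universe.
#' @export
combine_pathways <- function(...) {
  colls <- list(...)
  sets <- do.call(c, lapply(colls, `[[`, "sets"))
  if (anyDuplicated(names(sets))) stop("pathway id collision across collections")
  pathway_collection(sets,
                     name = do.call(c, lapply(colls, `[[`, "name")),
                     source = do.call(c, lapply(colls, `[[`, "source")))
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a miRNA target map
#'
#' TSV/CSV with columns `miRNA_id`, `target_id`, `evidence`
#' (validated/predicted) and `source`.
#'
#' @param path file path.
#' @return a `data.frame` of class `target_map`.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  as_target_map(df)
}

#' Validate a target map data frame
#' @param df data frame with miRNA_id, target_id, evidence, source columns.
#' @return validated `target_map`.
#' @export
as_target_map <- function(df) {
  need <- c("miRNA_id", "target_id", "evidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("target map lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$source)) df$source <- NA_character_
  bad <- setdiff(df$evidence, c("validated", "predicted"))
  if (length(bad) || any(is.na(df$evidence)))
    stop("evidence must be 'validated' or 'predicted' for every record")
  df <- df[!duplicated(df[c("miRNA_id", "target_id", "evidence")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_map", "data.frame")
  df
}

#' Merge miRNA target maps into one non-redundant map
#'
#' Duplicated (miRNA, target, evidence) triples are collapsed; a pair present
#' both as validated and predicted is kept once with evidence = validated, so
#' the stronger evidence level survives the merge.
#'
#' @param ... `target_map` data frames (or a single list of them).
#' @return merged `target_map`.
#' @export
merge_target_maps <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1L]]) && !is.data.frame(maps[[1L]]))
    maps <- maps[[1L]]
  all <- do.call(rbind, lapply(maps, function(m) as.data.frame(as_target_map(m))))
  # validated rows first so duplicated() on (miRNA, target) keeps them
  all <- all[order(all$evidence != "validated"), , drop = FALSE]
  all <- all[!duplicated(all[c("miRNA_id", "target_id")]), , drop = FALSE]
  all <- all[order(all$miRNA_id, all$target_id), , drop = FALSE]
  rownames(all) <- NULL
  class(all) <- c("target_map", "data.frame")
  all
}

#' Read a feature-to-gene map
#'
#' TSV/CSV with columns `feature_id`, `platform`, `gene_id`. A feature
#' mapping to several genes occupies several rows (expand behaviour); pass
#' `multi = "drop"` to discard ambiguous features instead.
#'
#' @param path file path.
#' @param multi `"expand"` (default) keeps all rows of multi-gene features,
#'   `"drop"` removes such features entirely.
#' @return a `data.frame` of class `gene_map`.
#' @export
read_gene_map <- function(path, multi = c("expand", "drop")) {
  df <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  as_gene_map(df, multi = multi)
}

#' Validate a gene map data frame
#' @inheritParams read_gene_map
#' @param df data frame with feature_id, platform, gene_id columns.
#' @return validated `gene_map`.
#' @export
as_gene_map <- function(df, multi = c("expand", "drop")) {
  multi <- match.arg(multi)
  need <- c("feature_id", "platform", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene map lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[!duplicated(df[need]), need, drop = FALSE]
  if (multi == "drop") {
    key <- paste(df$platform, df$feature_id)
    ambiguous <- unique(key[duplicated(key)])
    df <- df[!(paste(df$platform, df$feature_id) %in% ambiguous), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("gene_map", "data.frame")
  df
}

#' Binary class contrasts of the compound classification problem
#'
#' Three contrasts are defined: carcinogens (C = NGC and GC pooled) versus
#' non-carcinogens, NGC versus GC, and NGC versus NC. The first named side is
#' the positive class.
#'
#' @param name one of `"C_vs_NC"`, `"NGC_vs_GC"`, `"NGC_vs_NC"`.
#' @return a `contrast`: list with `name`, `positive`, `negative` (character
#'   vectors of class labels on each side).
#' @export
make_contrast <- function(name = c("C_vs_NC", "NGC_vs_GC", "NGC_vs_NC")) {
  name <- match.arg(name)
  sides <- switch(name,
    C_vs_NC   = list(positive = c("NGC", "GC"), negative = "NC"),
    NGC_vs_GC = list(positive = "NGC", negative = "GC"),
    NGC_vs_NC = list(positive = "NGC", negative = "NC"))
  structure(c(list(name = name), sides), class = "contrast")
}

#' Map class labels to contrast sides
#' @param contrast a [make_contrast()] object.
#' @param class_labels character vector of GC/NGC/NC/UNDEFINED labels.
#' @return factor with levels `c("neg", "pos")`; labels on neither side are `NA`.
#' @export
contrast_side <- function(contrast, class_labels) {
  out <- rep(NA_character_, length(class_labels))
  out[class_labels %in% contrast$positive] <- "pos"
  out[class_labels %in% contrast$negative] <- "neg"
  factor(out, levels = c("neg", "pos"))
}

#' Compare two gene signatures
#'
#' Reports the genes shared between a signature of interest and a reference
#' signature, and the overlap fraction relative to the first.
#'
#' @param sig_a,sig_b character vectors of gene ids.
#' @return list with `intersection`, `fraction` (|a ∩ b| / |a|; `NA` when
#'   `sig_a` is empty), `n_a`, `n_b`.
#' @export
compare_signatures <- function(sig_a, sig_b) {
  sig_a <- unique(sig_a); sig_b <- unique(sig_b)
  common <- intersect(sig_a, sig_b)
  list(intersection = common,
       fraction = if (length(sig_a) == 0L) NA_real_ else length(common) / length(sig_a),
       n_a = length(sig_a), n_b = length(sig_b))
}

#' Unified feature matrix with provenance tags
#'
#' Stacks numeric features (rows) over samples (columns); every feature
#' carries a provenance tag saying which layer it came from.
#'
#' @param values numeric matrix, features x samples, dimnames set.
#' @param provenance character vector, one of mRNA/miRNA/protein/MI/PE per row.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, provenance) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            length(provenance) == nrow(values))
  bad <- setdiff(unique(provenance), c("mRNA", "miRNA", "protein", "MI", "PE"))
  if (length(bad)) stop("unknown provenance tag(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(rownames(values))) stop("duplicated feature ids")
  structure(list(values = values,
                 provenance = stats::setNames(provenance, rownames(values))),
            class = "feature_matrix")
}

#' Row-stack feature matrices over identical samples
#' @param ... `feature_matrix` objects with identical sample columns.
#' @return stacked `feature_matrix`.
#' @export
stack_features <- function(...) {
  fms <- Filter(Negate(is.null), list(...))
  stopifnot(length(fms) >= 1L)
  ref <- colnames(fms[[1L]]$values)
  for (fm in fms)
    if (!identical(colnames(fm$values), ref))
      stop("feature matrices must share identical sample ids in identical order")
  feature_matrix(do.call(rbind, lapply(fms, `[[`, "values")),
                 unlist(lapply(fms, `[[`, "provenance"), use.names = FALSE))
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf("<feature_matrix> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Fold-change matrix as a single-platform feature matrix
#' @param fc a [fold_change_matrix()].
#' @return a `feature_matrix` tagged with the platform.
#' @export
as_feature_matrix <- function(fc) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  v <- fc$log_ratios
  rownames(v) <- paste(fc$platform, rownames(v), sep = ":")
  feature_matrix(v, rep(fc$platform, nrow(v)))
}
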