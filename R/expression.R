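#' Read a log2 expression matrix
#'
#' Reads a TSV whose first column holds row identifiers (probe sets or gene
#' symbols) and whose header names the samples. Values must be numeric with
#' no missing entries; duplicated row identifiers are an error.
#'
#' @param path Path to the expression TSV.
#' @return A tibble whose first column (`id`) holds the row identifiers and
#'   whose remaining columns hold one sample each.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3) {
    abort("expression matrix needs an id column and at least 2 samples")
  }
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated row id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  vals <- df[, -1, drop = FALSE]
  for (jj in seq_along(vals)) {
    col <- vals[[jj]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      abort(sprintf(
        "non-numeric value at row %d, column '%s'", bad, names(vals)[jj]
      ))
    }
    if (anyNA(col)) {
      abort(sprintf(
        "missing value at row %d, column '%s'", which(is.na(col))[1], names(vals)[jj]
      ))
    }
  }
  out <- tibble(id = ids)
  dplyr::bind_cols(out, vals)
}

#' Write an expression tibble as TSV
#' @param expr Expression tibble (id column first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

# internal: expression tibble -> numeric matrix with id rownames
expr_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- as.character(expr[[1]])
  storage.mode(m) <- "double"
  m
}

expr_samples <- function(expr) names(expr)[-1]

#' Three-stage probe filtering mask
#'
#' Flags each row of a log2 expression matrix for the filtering cascade used
#' before marker selection: rows with mean expression below `mean_min` are
#' deemed not (reliably) expressed, rows with sample standard deviation below
#' `sd_min` are uninformative, and among the rows of a gene passing both,
#' exactly the one with the highest mean expression is selected to represent
#' the gene (ties broken towards the lexicographically smallest row id).
#'
#' @param expr Expression tibble (first column row ids, remaining columns
#'   samples, log2 scale).
#' @param gene_map Optional data frame mapping row ids to gene symbols
#'   (columns: id, gene). When `NULL`, row ids are taken to be gene symbols
#'   already.
#' @param mean_min Minimum mean expression; rows strictly below fail
#'   (default 6 on the log2 scale).
#' @param sd_min Minimum sample standard deviation (n-1 denominator); rows
#'   strictly below fail (default 0.5).
#' @return A tibble with one row per input row: `id`, `gene`, `mean`, `sd`,
#'   `pass_expression`, `pass_variance`, `selected`.
#' @export
compute_filter_mask <- function(expr, gene_map = NULL, mean_min = 6, sd_min = 0.5) {
  m <- expr_values(expr)
  ids <- rownames(m)
  if (is.null(gene_map)) {
    gene <- ids
  } else {
    gene_map <- as.data.frame(gene_map)
    gidx <- match(ids, as.character(gene_map[[1]]))
    if (anyNA(gidx)) {
      abort(sprintf(
        "gene_map does not cover row id(s): %s",
        paste(head(ids[is.na(gidx)], 5), collapse = ", ")
      ))
    }
    gene <- as.character(gene_map[[2]])[gidx]
  }
  mu <- unname(rowMeans(m))
  s <- unname(apply(m, 1, sd))
  mask <- tibble(
    id = ids, gene = gene, mean = mu, sd = s,
    pass_expression = mu >= mean_min,
    pass_variance = s >= sd_min
  )
  # vectorized per-gene argmax: among passing rows, order by gene, then
  # decreasing mean, then id; the first row of each gene wins
  ok <- which(mask$pass_expression & mask$pass_variance)
  sel <- logical(nrow(mask))
  if (length(ok) > 0) {
    ord <- ok[order(mask$gene[ok], -mask$mean[ok], mask$id[ok])]
    sel[ord[!duplicated(mask$gene[ord])]] <- TRUE
  }
  mask$selected <- sel
  mask
}

#' Collapse probe sets to one row per gene
#'
#' Keeps the rows flagged `selected` by [compute_filter_mask()] (the
#' highest-mean passing probe set of each gene), relabels them with gene
#' symbols, and sorts by gene. Values are copied unchanged.
#'
#' @param expr Expression tibble the mask was computed on.
#' @param mask Result of [compute_filter_mask()].
#' @return A gene-level expression tibble (first column `gene`).
#' @export
collapse_probesets <- function(expr, mask) {
  if (!all(mask$id == as.character(expr[[1]]))) {
    abort("mask does not match the expression rows")
  }
  keep <- which(mask$selected)
  out <- expr[keep, , drop = FALSE]
  out[[1]] <- mask$gene[keep]
  names(out)[1] <- "gene"
  arrange(out, .data$gene)
}

#' Split survival times at the median into prognosis classes
#'
#' Patients surviving less than or equal to the median survival time form the
#' poor prognosis class; patients surviving longer form the good class.
#'
#' @param survival_months Positive survival times.
#' @return Character vector of `"poor"` / `"good"` labels.
#' @export
median_split <- function(survival_months) {
  if (length(survival_months) < 2) {
    abort("need at least 2 survival times")
  }
  if (length(unique(survival_months)) == 1) {
    abort("degenerate survival distribution: all survival times identical")
  }
  ifelse(survival_months <= median(survival_months), "poor", "good")
}

#' Read a clinical table and join it against the expression samples
#'
#' @param path TSV with columns `sample` and `survival_months` (optional
#'   additional columns such as `outcome` and `adjuvant` are carried along).
#' @param sample_ids Optional character vector of expression sample ids; when
#'   supplied, the clinical table must match it one-to-one and the result is
#'   ordered accordingly.
#' @param add_prognosis When `TRUE` (default) and no `prognosis` column is
#'   present, add one by [median_split()] of the survival times.
#' @return A cohort tibble with columns `sample`, `survival_months`,
#'   `prognosis`, plus any extra columns in the file.
#' @export
read_clinical_table <- function(path, sample_ids = NULL, add_prognosis = TRUE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "sample"
  df$sample <- as.character(df$sample)
  if (!"survival_months" %in% names(df)) {
    abort("clinical table must have a 'survival_months' column")
  }
  if (any(is.na(df$survival_months)) || any(df$survival_months <= 0)) {
    abort("survival_months must be positive and complete")
  }
  if (!is.null(sample_ids)) {
    missing_clin <- setdiff(sample_ids, df$sample)
    missing_expr <- setdiff(df$sample, sample_ids)
    if (length(missing_clin) || length(missing_expr)) {
      abort(sprintf(
        "sample mismatch; missing from clinical: [%s]; missing from expression: [%s]",
        paste(missing_clin, collapse = ", "),
        paste(missing_expr, collapse = ", ")
      ))
    }
    df <- df[match(sample_ids, df$sample), , drop = FALSE]
  }
  if (add_prognosis && !"prognosis" %in% names(df)) {
    df$prognosis <- median_split(df$survival_months)
  }
  as_tibble(df)
}
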