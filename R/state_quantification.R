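#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by the
#' Benjamini-Hochberg step-up false-discovery-rate procedure. Output order
#' matches input order; adjusted values are monotone in the raw values and lie
#' in \[0, 1\].
#'
#' @param p_values numeric vector of probabilities in \[0, 1\].
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Criteria for calling a significant expression change
#'
#' The default criteria require a BH-adjusted p-value of at most 0.05 and an
#' absolute linear fold change of at least 1.3. An alternative regime used for
#' noisy high-change comparisons is an unadjusted p-value cutoff of 0.01 with
#' no fold-change criterion:
#' `change_criteria("unadjusted", 0.01, NULL)`.
#'
#' @param p_mode `"adjusted_bh"` (test BH-adjusted p) or `"unadjusted"`.
#' @param p_cutoff p-value cutoff, in (0, 1).
#' @param min_abs_fold_change minimum linear fold change, applied to
#'   `max(r, 1/r)`; `NULL` disables the fold criterion.
#' @return an object of class `change_criteria`.
#' @export
change_criteria <- function(p_mode = c("adjusted_bh", "unadjusted"),
                            p_cutoff = 0.05, min_abs_fold_change = 1.3) {
  p_mode <- match.arg(p_mode)
  stopifnot(is.numeric(p_cutoff), length(p_cutoff) == 1L,
            p_cutoff > 0, p_cutoff < 1)
  if (!is.null(min_abs_fold_change)) {
    stopifnot(is.numeric(min_abs_fold_change), length(min_abs_fold_change) == 1L)
    if (min_abs_fold_change < 1) stop("min_abs_fold_change must be >= 1")
  }
  structure(list(p_mode = p_mode, p_cutoff = p_cutoff,
                 min_abs_fold_change = min_abs_fold_change),
            class = "change_criteria")
}

#' Bundle a replicate expression matrix with its design
#'
#' @param matrix numeric genes x samples matrix of log2-scale expression
#'   values with gene identifiers as rownames and sample identifiers as
#'   colnames.
#' @param design data.frame with columns `sample`, `group`; every sample in
#'   the matrix must be annotated, groups are `"treated"` and `"control"`,
#'   each with at least 2 replicates. Samples from pooled timepoints are
#'   simply listed as additional replicates of their group.
#' @param name experiment name (cell line / model / timepoint comparison).
#' @return an object of class `expression_experiment`.
#' @export
expression_experiment <- function(matrix, design, name = "experiment") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  g <- rownames(matrix)
  if (is.null(g) || any(is.na(g)) || any(!nzchar(g)))
    stop("matrix must have non-empty gene identifiers as rownames")
  if (anyDuplicated(g)) stop("duplicate gene rows rejected: ",
                             g[anyDuplicated(g)])
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(design)))
  design$sample <- as.character(design$sample)
  design$group <- as.character(design$group)
  if (!setequal(colnames(matrix), design$sample))
    stop("design samples must match matrix columns")
  design <- design[match(colnames(matrix), design$sample), , drop = FALSE]
  bad <- setdiff(unique(design$group), c("treated", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  cnt <- table(factor(design$group, levels = c("treated", "control")))
  if (any(cnt < 2L)) stop("each group needs at least 2 replicates")
  rownames(design) <- NULL
  structure(list(matrix = matrix, design = design, name = name),
            class = "expression_experiment")
}

#' Read an expression experiment from TSV files
#'
#' The matrix file is tab-separated with first column `gene` and one column
#' per sample; the design file has columns `sample` and `group`.
#'
#' @param matrix_path,design_path file paths.
#' @param name experiment name; defaults to the matrix file base name.
#' @return an [expression_experiment] object.
#' @export
read_expression_experiment <- function(matrix_path, design_path, name = NULL) {
  for (p in c(matrix_path, design_path))
    if (!file.exists(p)) stop("no such file: ", p)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(matrix_path))
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene") stop("matrix file must have first column 'gene'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab$gene)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  expression_experiment(m, design, name = name)
}

## Row-wise group means and variances. eps is added to the variance of the
## mean difference so that planted exact fixtures (zero within-group variance)
## yield p ~ 0 when means differ and p = 1 when they agree, rather than 0/0.
.row_group_stats <- function(m, idx) {
  n <- length(idx)
  mu <- rowMeans(m[, idx, drop = FALSE])
  v <- rowSums((m[, idx, drop = FALSE] - mu)^2) / max(1L, n - 1L)
  list(mu = mu, v = v, n = n)
}

.welch_rows <- function(m, i_trt, i_ctl, eps = 1e-9) {
  a <- .row_group_stats(m, i_trt)
  b <- .row_group_stats(m, i_ctl)
  se2 <- a$v / a$n + b$v / b$n + eps
  tstat <- (a$mu - b$mu) / sqrt(se2)
  denom <- a$v^2 / (a$n^2 * (a$n - 1)) + b$v^2 / (b$n^2 * (b$n - 1))
  df <- ifelse(denom > 0, se2^2 / denom, a$n + b$n - 2)
  p <- 2 * stats::pt(-abs(tstat), df)
  list(p = p, diff = a$mu - b$mu)
}

.anova_rows <- function(m, groups, eps = 1e-9) {
  gl <- unique(groups)
  k <- length(gl)
  N <- length(groups)
  gm <- rowMeans(m)
  ssb <- 0
  ssw <- 0
  for (g in gl) {
    s <- .row_group_stats(m, which(groups == g))
    ssb <- ssb + s$n * (s$mu - gm)^2
    ssw <- ssw + (s$n - 1) * s$v
  }
  fstat <- (ssb / (k - 1)) / (ssw / (N - k) + eps)
  stats::pf(fstat, k - 1, N - k, lower.tail = FALSE)
}

#' Call signed RNA state changes from a replicate expression experiment
#'
#' Performs a per-gene treated-vs-control test on the log2 expression matrix,
#' adjusts p-values by Benjamini-Hochberg, and reduces each gene to one of
#' `increase`, `decrease`, or `no_change`: a gene is called changed iff its
#' p-value (adjusted or raw, per the criteria) is at most `p_cutoff` and, when
#' a fold criterion is set, `max(r, 1/r) >= min_abs_fold_change`, where
#' `r = 2^(mean treated - mean control)` is the linear fold change. Direction
#' follows the sign of the fold change.
#'
#' Genes with identical values in both groups get p = 1 (no change). A small
#' epsilon (1e-9) is added to the variance of the mean difference so that
#' zero-variance genes with differing means are called with p near 0 rather
#' than failing.
#'
#' @param exp an [expression_experiment].
#' @param criteria a [change_criteria] object.
#' @param test `"two_sample_t"` (Welch) or `"one_way_anova"` (equal-variance
#'   F; identical hypothesis for the two-group designs used here).
#' @return data.frame of class `state_change_set` with one row per gene:
#'   columns `entity`, `aspect` (`"rna_abundance"`), `direction`,
#'   `fold_change` (linear ratio; > 1 up, < 1 down), `p_raw`, `p_adjusted`.
#' @export
call_rna_state_changes <- function(exp, criteria = change_criteria(),
                                   test = c("two_sample_t", "one_way_anova")) {
  stopifnot(inherits(exp, "expression_experiment"),
            inherits(criteria, "change_criteria"))
  test <- match.arg(test)
  m <- exp$matrix
  grp <- exp$design$group
  i_trt <- which(grp == "treated")
  i_ctl <- which(grp == "control")
  mt <- rowMeans(m[, i_trt, drop = FALSE])
  mc <- rowMeans(m[, i_ctl, drop = FALSE])
  if (test == "two_sample_t") {
    p_raw <- .welch_rows(m, i_trt, i_ctl)$p
  } else {
    p_raw <- .anova_rows(m, grp)
  }
  ## exact-tie convention: identical group values carry no evidence of change
  p_raw[mt == mc] <- 1
  p_adj <- bh_adjust(p_raw)
  p_use <- if (criteria$p_mode == "adjusted_bh") p_adj else p_raw
  r <- 2^(mt - mc)
  absfold <- pmax(r, 1 / r)
  changed <- p_use <= criteria$p_cutoff
  if (!is.null(criteria$min_abs_fold_change))
    changed <- changed & absfold >= criteria$min_abs_fold_change
  changed <- changed & r != 1
  direction <- ifelse(!changed, "no_change",
                      ifelse(r > 1, "increase", "decrease"))
  out <- data.frame(entity = rownames(m), aspect = "rna_abundance",
                    direction = direction, fold_change = unname(r),
                    p_raw = unname(p_raw), p_adjusted = unname(p_adj),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("state_change_set", "data.frame")
  out
}

#' Read a phosphoprotein treated/vehicle ratio table
#'
#' TSV with columns `entity`, `modification`, `timepoint`, `ratio`.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_phospho_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("entity", "modification", "timepoint", "ratio") %in% names(tab)))
  tab
}

#' Call phosphoprotein state changes from treated/vehicle ratios
#'
#' A phospho analyte is called `decrease` when the treated/vehicle ratio shows
#' at least a 20 percent decrease (ratio <= 0.80 by default) and `increase`
#' when it shows at least a 50 percent increase (ratio >= 1.50); otherwise
#' `no_change`. The thresholds are deliberately asymmetric; boundaries are
#' inclusive. No p-values are attached.
#'
#' @param table data.frame with columns `entity`, `timepoint`, `ratio`
#'   (positive treated/vehicle ratios); a `modification` column is carried
#'   through if present.
#' @param decrease_threshold fractional decrease calling a change
#'   (default 0.20, i.e. ratio <= 0.80).
#' @param increase_threshold fractional increase calling a change
#'   (default 0.50, i.e. ratio >= 1.50).
#' @return `state_change_set` data.frame, one row per input row, aspect
#'   `"protein_modification"`, `fold_change` = the ratio, p fields `NA`.
#' @export
call_phospho_state_changes <- function(table, decrease_threshold = 0.20,
                                       increase_threshold = 0.50) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("entity", "ratio") %in% names(table)),
            decrease_threshold > 0, decrease_threshold < 1,
            increase_threshold > 0)
  ratio <- as.numeric(table$ratio)
  if (anyNA(ratio) || any(ratio <= 0)) stop("ratios must be positive")
  lo <- 1 - decrease_threshold
  hi <- 1 + increase_threshold
  direction <- ifelse(ratio <= lo, "decrease",
                      ifelse(ratio >= hi, "increase", "no_change"))
  out <- data.frame(entity = as.character(table$entity),
                    aspect = "protein_modification",
                    direction = direction, fold_change = ratio,
                    p_raw = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("state_change_set", "data.frame")
  out
}

#' Merge RNA and phosphoproteomic state changes into one evidence set
#'
#' Takes the union of the two sets. If the same node (same entity and aspect)
#' appears with conflicting changed directions — e.g. a phospho analyte up at
#' one timepoint and down at another — the node is dropped and the conflict
#' recorded (attribute `"conflicts"`, plus a warning). Duplicate rows with
#' agreeing direction collapse to a single row (the first changed row is
#' kept).
#'
#' @param rna,phospho `state_change_set` data.frames (either may be `NULL`).
#' @return merged `state_change_set` with attribute `conflicts` (character
#'   vector of dropped node keys).
#' @export
merge_state_changes <- function(rna, phospho = NULL) {
  all <- rbind(as.data.frame(rna), as.data.frame(phospho))
  if (is.null(all) || nrow(all) == 0L) {
    out <- data.frame(entity = character(), aspect = character(),
                      direction = character(), fold_change = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("state_change_set", "data.frame")
    attr(out, "conflicts") <- character()
    return(out)
  }
  key <- node_key(all$entity, all$aspect)
  keep <- integer()
  conflicts <- character()
  for (k in unique(key)) {
    rows <- which(key == k)
    dirs <- unique(all$direction[rows])
    dirs <- setdiff(dirs, "no_change")
    if (length(dirs) > 1L) {
      conflicts <- c(conflicts, k)
    } else if (length(dirs) == 1L) {
      keep <- c(keep, rows[which(all$direction[rows] == dirs)[1]])
    } else {
      keep <- c(keep, rows[1])
    }
  }
  if (length(conflicts))
    warning("dropping node(s) with conflicting directions: ",
            paste(conflicts, collapse = ", "))
  out <- all[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("state_change_set", "data.frame")
  attr(out, "conflicts") <- conflicts
  out
}

#' Measured universe of a set of state-change calls
#'
#' The measured universe is the set of all (entity, aspect) nodes that were
#' measured in an experiment — every gene on the array plus every phospho
#' analyte — regardless of whether they changed. It is the population size N
#' of the Richness statistic.
#'
#' @param changes a `state_change_set` containing one row per measured node
#'   (changed or not).
#' @return data.frame with columns `entity`, `aspect`, unique rows.
#' @export
universe_from_changes <- function(changes) {
  u <- unique(data.frame(entity = changes$entity, aspect = changes$aspect,
                         stringsAsFactors = FALSE))
  u <- u[order(u$entity, u$aspect), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Write / read a state-change table as TSV
#'
#' Columns `entity aspect direction fold_change p_raw p_adjusted`.
#'
#' @param changes `state_change_set` data.frame.
#' @param path file path.
#' @return `path` (write) or the `state_change_set` (read).
#' @export
write_state_changes <- function(changes, path) {
  utils::write.table(as.data.frame(changes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_changes
#' @export
read_state_changes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("state_change_set", "data.frame")
  out
}
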