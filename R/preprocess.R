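#' Univariate Cox screening of binary mutation features
#'
#' Zero-prevalence genes (never mutated in the cohort) are removed before
#' testing. Each remaining gene enters a single-covariate Cox
#' proportional-hazards fit (Breslow ties) and its Wald p-value is
#' recorded; genes with `p < alpha` are selected, in original column order.
#'
#' @param mutations patients x genes binary matrix (0/1) with gene column
#'   names.
#' @param outcomes data frame with `time`, `event`, aligned to the rows.
#' @param alpha selection level in (0, 1); default 0.05.
#' @return list with `selected` (character vector of gene names),
#'   `p_values` (named, one per tested gene) and `dropped_zero_prevalence`.
#' @export
screen_mutations <- function(mutations, outcomes, alpha = 0.05) {
  mutations <- as.matrix(mutations)
  if (!all(mutations %in% c(0, 1)))
    stop_cms("mutation matrix must be binary 0/1")
  outcomes <- check_outcomes(outcomes)
  if (nrow(mutations) != nrow(outcomes))
    stop_cms("mutations and outcomes are not aligned")
  check_prob(alpha, "alpha")
  if (is.null(colnames(mutations)))
    colnames(mutations) <- sprintf("gene_%03d", seq_len(ncol(mutations)))

  zero <- colSums(mutations) == 0
  kept <- colnames(mutations)[!zero]
  if (!length(kept)) {
    warning("all genes have zero prevalence; empty selection", call. = FALSE)
    return(list(selected = character(), p_values = setNames(numeric(), character()),
                dropped_zero_prevalence = colnames(mutations)[zero]))
  }
  srv <- survival::Surv(outcomes$time, outcomes$event)
  pv <- vapply(kept, function(g) {
    x <- mutations[, g]
    if (all(x == x[1])) return(NA_real_)  # constant after alignment
    fit <- tryCatch(
      survival::coxph(srv ~ x, ties = "breslow"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(srv ~ x, ties = "breslow"))
      })
    if (is.null(fit)) return(NA_real_)
    s <- summary(fit)$coefficients
    unname(s[1, "Pr(>|z|)"])
  }, numeric(1))
  selected <- kept[!is.na(pv) & pv < alpha]
  list(selected = selected, p_values = pv,
       dropped_zero_prevalence = colnames(mutations)[zero])
}

#' Fit-or-apply construction of the model-ready feature matrix
#'
#' Clinical tables mix continuous and categorical columns. On a first call
#' (no `state`), per-column statistics are fitted on the given table:
#' means/SDs for continuous columns (mean imputation then z-scoring with
#' the sample SD, denominator n-1), observed level lists and modes for
#' categorical columns (one indicator column per level, optionally an
#' explicit `"missing"` level). On later calls the fitted `state` is
#' applied unchanged — transform never refits, which is what makes
#' fold-wise preprocessing leakage-safe.
#'
#' @param clinical data frame, patients in rows (row names = patient ids).
#' @param schema named character vector mapping column name ->
#'   `"continuous"` or `"categorical"`. Defaults to numeric columns
#'   continuous, everything else categorical.
#' @param state a previously fitted state, or `NULL` to fit.
#' @param missing_category add an explicit `"missing"` indicator level for
#'   categorical NAs (otherwise NAs are imputed by the fitted mode)?
#' @return list with `features` (numeric matrix) and `state`.
#' @export
build_feature_matrix <- function(clinical, schema = NULL, state = NULL,
                                 missing_category = TRUE) {
  if (!is.data.frame(clinical)) stop_cms("clinical must be a data frame")
  fitting <- is.null(state)
  if (fitting) {
    if (is.null(schema)) {
      schema <- vapply(clinical, function(x)
        if (is.numeric(x)) "continuous" else "categorical", character(1))
    }
    state <- list(schema = schema, missing_category = missing_category,
                  continuous = list(), categorical = list())
    for (nm in names(schema)) {
      x <- clinical[[nm]]
      if (is.null(x)) stop_cms("schema column '", nm, "' absent from table")
      if (schema[[nm]] == "continuous") {
        mu <- mean(x, na.rm = TRUE)
        if (is.nan(mu)) mu <- 0
        sdev <- sd(x, na.rm = TRUE)
        constant <- is.na(sdev) || sdev < 1e-12
        if (constant) sdev <- 1  # constant column: becomes all zeros
        state$continuous[[nm]] <- list(mean = mu, sd = sdev,
                                       constant = constant)
      } else {
        x <- as.character(x)
        lev <- sort(unique(x[!is.na(x)]))
        mode_lv <- if (length(lev)) {
          tb <- table(x)
          names(tb)[which.max(tb)]
        } else "missing"
        if (missing_category && anyNA(clinical[[nm]]))
          lev <- c(lev, "missing")
        state$categorical[[nm]] <- list(levels = lev, mode = mode_lv)
      }
    }
    class(state) <- "cms_preprocess_state"
  }

  cols <- list()
  n <- nrow(clinical)
  for (nm in names(state$schema)) {
    kind <- state$schema[[nm]]
    x <- clinical[[nm]]
    if (is.null(x)) stop_cms("column '", nm, "' absent from table")
    if (kind == "continuous") {
      st <- state$continuous[[nm]]
      x <- as.numeric(x)
      x[is.na(x)] <- st$mean
      z <- (x - st$mean) / st$sd
      if (st$constant) z <- rep(0, n)
      cols[[nm]] <- matrix(z, ncol = 1, dimnames = list(NULL, nm))
    } else {
      st <- state$categorical[[nm]]
      x <- as.character(x)
      if (state$missing_category && "missing" %in% st$levels)
        x[is.na(x)] <- "missing"
      else x[is.na(x)] <- st$mode
      unseen <- setdiff(unique(x), st$levels)
      if (length(unseen))
        message("column '", nm, "': unseen level(s) ",
                paste(unseen, collapse = ", "), " mapped to all-zero indicators")
      M <- vapply(st$levels, function(lv) as.numeric(x == lv), numeric(n))
      if (n == 1L) M <- matrix(M, nrow = 1)
      colnames(M) <- paste0(nm, "=", st$levels)
      cols[[nm]] <- M
    }
  }
  features <- do.call(cbind, cols)
  rownames(features) <- rownames(clinical)
  list(features = features, state = state)
}

#' Align a mutation matrix to a fitted gene selection
#'
#' Genes selected on the training cohort but absent from a (typically
#' external) matrix are zero-filled, mirroring deployment on cohorts
#' sequenced with narrower panels; extra genes are dropped.
#'
#' @param mutations patients x genes binary matrix.
#' @param selected character vector of gene names fixing column order.
#' @return patients x `length(selected)` binary matrix.
#' @export
align_mutation_features <- function(mutations, selected) {
  mutations <- as.matrix(mutations)
  out <- matrix(0, nrow(mutations), length(selected),
                dimnames = list(rownames(mutations), selected))
  common <- intersect(selected, colnames(mutations))
  if (length(common) < length(selected))
    message(length(selected) - length(common),
            " selected gene(s) absent from matrix; zero-filled")
  out[, common] <- mutations[, common]
  out
}

#' Read a MAF file into a binary patient x gene mutation matrix
#'
#' Standard Mutation Annotation Format columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification` are collapsed to
#' presence/absence per patient and gene, excluding the configured variant
#' classes.
#'
#' @param path MAF file (tab-separated, `#` comments allowed).
#' @param exclude_classes variant classes that do not count as mutations;
#'   default `"Silent"`.
#' @param patient_ids optional ids fixing row order (absent patients get
#'   all-zero rows).
#' @return binary matrix, patients x genes.
#' @export
read_maf_binary <- function(path, exclude_classes = "Silent",
                            patient_ids = NULL) {
  maf <- read.csv(path, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  if (!all(need %in% names(maf)))
    stop_cms("MAF file lacks required columns: ",
             paste(setdiff(need, names(maf)), collapse = ", "))
  maf <- maf[!maf$Variant_Classification %in% exclude_classes, , drop = FALSE]
  pts <- patient_ids %||% sort(unique(maf$Tumor_Sample_Barcode))
  genes <- sort(unique(maf$Hugo_Symbol))
  M <- matrix(0L, length(pts), length(genes), dimnames = list(pts, genes))
  hit <- unique(maf[, c("Tumor_Sample_Barcode", "Hugo_Symbol")])
  hit <- hit[hit$Tumor_Sample_Barcode %in% pts, , drop = FALSE]
  M[cbind(match(hit$Tumor_Sample_Barcode, pts),
          match(hit$Hugo_Symbol, genes))] <- 1L
  M
}
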