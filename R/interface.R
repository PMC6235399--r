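## Dataset I/O and validation, multiple-testing helper, results tables.
##
## On-disk layout: plain TSVs with a header row. The count tables (alt,
## depth, calls) have site ids in the first column ("chr:pos", 1-based) and
## one column per sample; the outcome table has sample_id, Y, then
## covariates; an optional sites table maps site_id to gene.

.readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read and validate a mutation dataset
#'
#' Reads the alternative-count, depth, call and outcome tables, checks that
#' sample ids agree across files (fatal on mismatch, naming the offenders),
#' rejects cells with A > D (naming them), and coerces calls at depth < d0
#' to missing with a logged count. After validation, calls are missing
#' exactly where depth < d0.
#'
#' @param altFile,depthFile,callsFile TSV paths (sites x samples; first
#'   column site_id)
#' @param outcomeFile TSV path with columns sample_id, Y, then covariates
#' @param sitesFile optional TSV path with columns site_id, gene
#' @param d0 calling depth threshold
#' @return a list with matrices \code{A}, \code{D}, \code{O}, vector
#'   \code{Y}, matrix \code{X} (NULL if no covariates), \code{sampleIds},
#'   \code{siteIds}, \code{genes}, and \code{coercedCalls} (count of calls
#'   blanked at low depth)
#' @export
readDataset <- function(altFile, depthFile, callsFile, outcomeFile,
                        sitesFile = NULL, d0 = 20) {
  A <- .readMatrixTSV(altFile)
  D <- .readMatrixTSV(depthFile)
  O <- .readMatrixTSV(callsFile)
  pheno <- utils::read.delim(outcomeFile, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "Y") %in% names(pheno)))
    stop("outcome table must have columns sample_id and Y")
  ids <- colnames(A)
  for (nm in list(c("depth", "alt"), c("calls", "alt"))) {
    other <- if (nm[1L] == "depth") colnames(D) else colnames(O)
    if (!identical(other, ids)) {
      bad <- union(setdiff(other, ids), setdiff(ids, other))
      stop("sample ids differ between ", nm[1L], " and ", nm[2L],
           " tables: ", paste(bad, collapse = ", "))
    }
  }
  if (!setequal(pheno$sample_id, ids))
    stop("sample ids differ between outcome and count tables: ",
         paste(union(setdiff(pheno$sample_id, ids),
                     setdiff(ids, pheno$sample_id)), collapse = ", "))
  pheno <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  if (!identical(rownames(D), rownames(A)) ||
      !identical(rownames(O), rownames(A)))
    stop("site ids differ across count tables")
  bad <- which(A > D, arr.ind = TRUE)
  if (nrow(bad))
    stop("alternative count exceeds depth at ",
         paste(sprintf("(%s, %s)", rownames(A)[bad[, 1L]],
                       colnames(A)[bad[, 2L]]), collapse = ", "))
  lowCalled <- which(D < d0 & !is.na(O))
  if (length(lowCalled)) {
    message(length(lowCalled), " call(s) at depth < d0 coerced to missing")
    O[lowCalled] <- NA_integer_
  }
  highMissing <- which(D >= d0 & is.na(O), arr.ind = TRUE)
  if (nrow(highMissing))
    stop("call missing at depth >= d0 at ",
         paste(sprintf("(%s, %s)", rownames(A)[highMissing[, 1L]],
                       colnames(A)[highMissing[, 2L]]), collapse = ", "))
  genes <- rep(NA_character_, nrow(A))
  if (!is.null(sitesFile)) {
    st <- utils::read.delim(sitesFile, stringsAsFactors = FALSE)
    genes <- st$gene[match(rownames(A), st$site_id)]
  }
  covCols <- setdiff(names(pheno), c("sample_id", "Y"))
  storage.mode(A) <- "integer"; storage.mode(D) <- "integer"
  storage.mode(O) <- "integer"
  list(A = A, D = D, O = O, Y = pheno$Y,
       X = if (length(covCols))
         as.matrix(pheno[, covCols, drop = FALSE]) else NULL,
       sampleIds = ids, siteIds = rownames(A), genes = genes,
       coercedCalls = length(lowCalled))
}

#' Write a mutation dataset as TSV tables
#'
#' Inverse of \code{\link{readDataset}}; writing then reading reproduces
#' the dataset exactly.
#'
#' @param dataset a list as returned by \code{\link{readDataset}}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    df <- data.frame(site_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wm(dataset$A, "alt.tsv"); wm(dataset$D, "depth.tsv")
  wm(dataset$O, "calls.tsv")
  ph <- data.frame(sample_id = dataset$sampleIds, Y = dataset$Y,
                   check.names = FALSE)
  if (!is.null(dataset$X)) ph <- cbind(ph, dataset$X)
  utils::write.table(ph, file.path(dir, "outcomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(site_id = dataset$siteIds, gene = dataset$genes),
    file.path(dir, "sites.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1)
#' @param nTests number of tests, >= 1
#' @return alpha / nTests
#' @examples
#' bonferroniThreshold(0.05, 37 * 16339)
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Results table for a list of test results
#'
#' Assembles the standard TSV schema from \code{\link{SameTest}} and/or
#' \code{\link{WaldResult}} objects: id, method, beta_hat, T, pvalue,
#' rho1_hat, n_iter, converged.
#'
#' @param tests named list of \code{SameTest} / \code{WaldResult} objects
#'   (names become ids for WaldResults)
#' @param file optional TSV path to write
#' @return a data.frame (invisibly when written)
#' @export
resultsTable <- function(tests, file = NULL) {
  rows <- lapply(seq_along(tests), function(i) {
    x <- tests[[i]]
    if (is(x, "SameTest")) {
      data.frame(id = x@id,
                 method = if (x@fitAlt@level == "gene") "gSAME" else "mSAME",
                 beta_hat = x@fitAlt@outcome@beta, T = x@statistic,
                 pvalue = x@pvalue, rho1_hat = x@fitAlt@rho1,
                 n_iter = x@fitAlt@nIter, converged = x@fitAlt@converged)
    } else {
      data.frame(id = if (!is.null(names(tests))) names(tests)[i] else
                   as.character(i),
                 method = "GLM", beta_hat = x@betaHat, T = x@z^2,
                 pvalue = x@pvalue, rho1_hat = NA_real_, n_iter = NA_integer_,
                 converged = NA)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
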