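#' Read an expression matrix from delimited text
#'
#' Reads a tab-delimited expression table, auto-detecting the GCT dialect
#' (a "#1.2" version line followed by a dimensions line, then Name /
#' Description columns). The matrix is returned features-by-samples
#' internally regardless of the file orientation.
#'
#' @param path file path.
#' @param orientation \code{"features"} if file rows are features (default)
#'   or \code{"samples"} if the file is transposed.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
readExpressionMatrix <- function(path, orientation = c("features",
                                                       "samples")) {
  orientation <- match.arg(orientation)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file: ", path)
  if (startsWith(first, "#1.")) {             # GCT dialect
    message("GCT version ", sub("^#", "", first))
    tab <- read.delim(path, skip = 2L, check.names = FALSE,
                      stringsAsFactors = FALSE)
    feat <- as.character(tab[[1]])
    m <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    feat <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
  }
  if (!nrow(m)) stop("no data rows in ", path)
  if (anyDuplicated(feat))
    stop("duplicate feature names: ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    stop("non-numeric cell(s), first at row ", bad[1, 1], " column ",
         bad[1, 2] + 1L)
  }
  rownames(m) <- feat
  if (orientation == "samples") m <- t(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param m numeric matrix, features x samples.
#' @param path output path.
#' @param idColumn header of the feature-name column.
#' @export
writeExpressionMatrix <- function(m, path, idColumn = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a registry table
#'
#' Plain TSV with the [simulateRegistry()] column schema; missing clinical
#' fields are empty strings, never sentinel numbers.
#'
#' @param registry registry data.frame.
#' @param path file path.
#' @return \code{readRegistry} returns the registry data.frame.
#' @export
writeRegistry <- function(registry, path) {
  write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' @rdname writeRegistry
#' @export
readRegistry <- function(path) {
  reg <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chemo_agents = "character"))
  reg$chemo_agents[is.na(reg$chemo_agents)] <- ""
  for (col in c("surgery", "radiation", "preop_radiation"))
    if (col %in% names(reg)) reg[[col]] <- as.logical(reg[[col]])
  reg
}

#' Export a survival curve as two-column TSV
#'
#' @param curve a [SurvivalCurve-class].
#' @param path output path.
#' @export
writeSurvivalCurve <- function(curve, path) {
  write.table(data.frame(time = curve@time, survival = curve@surv),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
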