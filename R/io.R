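# Plain-text interchange: genotype, map, phenotype and GRM tables as TSV.

#' Write and read panel genotypes as TSV
#'
#' Genotype tables have one row per line with columns \code{line},
#' \code{population}, then one column per marker (values -1/0/+1, header row
#' of marker names). Map tables have columns \code{marker}, \code{chromosome},
#' \code{position_cM}. Phenotype tables have \code{line}, \code{population},
#' then one column per environment with \code{NA} for missing cells.
#'
#' @param panel a \linkS4class{NAMPanel}.
#' @param file path to write.
#' @return \code{writeGenotypesTSV} returns \code{file} invisibly;
#'   \code{readGenotypesTSV} returns a list with \code{geno} (matrix,
#'   line-id rownames), \code{lineIds} and \code{popIds}.
#' @name genotype-io
#' @export
writeGenotypesTSV <- function(panel, file) {
  g <- genotypes(panel)
  df <- data.frame(line = lineIds(panel), population = populationIds(panel),
                   g, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname genotype-io
#' @export
readGenotypesTSV <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(geno) <- df$line
  list(geno = geno, lineIds = df$line, popIds = df$population)
}

#' @rdname genotype-io
#' @param map a \linkS4class{GeneticMap}.
#' @export
writeMapTSV <- function(map, file) {
  write.table(data.frame(marker = map@marker, chromosome = map@chrom,
                         position_cM = map@pos),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname genotype-io
#' @export
readMapTSV <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  new("GeneticMap", marker = as.character(df$marker),
      chrom = as.character(df$chromosome), pos = df$position_cM)
}

#' @rdname genotype-io
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @export
writePhenotypesTSV <- function(pheno, file) {
  df <- data.frame(line = pheno@lineIds, population = pheno@popIds,
                   pheno@values, check.names = FALSE)
  colnames(df)[-(1:2)] <- pheno@env
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(file)
}

#' @rdname genotype-io
#' @export
readPhenotypesTSV <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  new("PhenotypeTable", lineIds = as.character(df$line),
      popIds = as.character(df$population),
      env = colnames(df)[-(1:2)], values = unname(vals),
      mask = unname(is.na(vals)))
}

#' @rdname genotype-io
#' @param A a relationship matrix from \code{\link{computeGRM}}.
#' @export
writeGRMTSV <- function(A, file) {
  meta <- sprintf("# denom=%s markers=%s",
                  format(attr(A, "denom") %||% NA),
                  format(attr(A, "markers") %||% ""))
  writeLines(meta, file)
  df <- data.frame(line = rownames(A) %||% paste0("l", seq_len(nrow(A))), A,
                   check.names = FALSE)
  suppressWarnings(write.table(df, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(file)
}
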