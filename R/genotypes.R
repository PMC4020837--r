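#' Genotype tables
#'
#' A `genotype_table` stores diploid STR calls: one row per individual with an
#' individual id, a population label, and two allele columns per locus named
#' `<locus>_1` and `<locus>_2`. Allele labels are opaque text (microvariant
#' repeat labels such as `"9.3"` are never coerced to numbers); a missing call
#' is `NA` in *both* slots — a half-missing genotype (one allele present, the
#' other missing) is invalid.
#'
#' @param data data.frame with columns `individual_id`, `population` and a
#'   `<locus>_1`/`<locus>_2` pair per locus (character).
#' @param loci Ordered character vector of locus names. Defaults to the loci
#'   implied by the paired columns of `data`, in column order.
#' @return A `genotype_table`: the validated data.frame with class
#'   `c("genotype_table", "data.frame")` and attribute `loci`.
#' @examples
#' gt <- genotype_table(data.frame(
#'   individual_id = c("i1", "i2"), population = "P1",
#'   TH01_1 = c("6", "9.3"), TH01_2 = c("7", "9.3"),
#'   stringsAsFactors = FALSE
#' ))
#' gt_loci(gt)
#' @export
genotype_table <- function(data, loci = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("individual_id", "population") %in% names(data))) {
    stop_strpop("genotype data must have 'individual_id' and 'population' columns")
  }
  if (is.null(loci)) {
    a1 <- grep("_1$", names(data), value = TRUE)
    loci <- sub("_1$", "", a1)
    loci <- loci[paste0(loci, "_2") %in% names(data)]
  }
  if (length(loci) == 0L) stop_strpop("no loci found (need <locus>_1/<locus>_2 column pairs)")
  if (anyDuplicated(loci)) stop_strpop("duplicate locus names: ",
                                       paste(unique(loci[duplicated(loci)]), collapse = ", "))
  cols <- c("individual_id", "population",
            as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) stop_strpop("missing columns: ", paste(missing_cols, collapse = ", "))
  data <- data[, cols, drop = FALSE]
  for (cl in cols) data[[cl]] <- as.character(data[[cl]])
  if (any(is.na(data$population) | data$population == "")) {
    stop_strpop("empty population label in rows: ",
                paste(which(is.na(data$population) | data$population == ""), collapse = ", "))
  }
  # half-missing rule
  for (l in loci) {
    a <- data[[paste0(l, "_1")]]
    b <- data[[paste0(l, "_2")]]
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      i <- which(half)[1L]
      stop_strpop("half-missing genotype for individual '", data$individual_id[i],
                  "' at locus '", l, "'", class = "strpop_validation_error")
    }
  }
  structure(data, loci = loci, class = c("genotype_table", "data.frame"))
}

#' @rdname genotype_table
#' @param x A `genotype_table`.
#' @export
gt_loci <- function(x) attr(x, "loci")

#' @rdname genotype_table
#' @export
gt_populations <- function(x) unique(x$population)

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals, %d populations, %d loci\n",
              nrow(x), length(gt_populations(x)), length(gt_loci(x))))
  cat("loci:", paste(gt_loci(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write genotype tables
#'
#' Delimited-text layout: a header row with `individual_id`, `population` and
#' two columns per locus (`<locus>_1`, `<locus>_2`). Ragged rows are a parse
#' error naming the offending line; half-missing genotypes are a validation
#' error naming the individual and locus.
#'
#' @param path File path.
#' @param sep Field delimiter (default `","`).
#' @param missing Strings normalized to the missing sentinel `NA`
#'   (default `c("", "NA")`).
#' @return `read_genotypes()` returns a [genotype_table()];
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path, sep = ",", missing = c("", "NA")) {
  if (!file.exists(path)) stop_strpop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop_strpop("malformed row at line ", bad, ": expected ", nf[1L],
                " fields, found ", nf[bad], class = "strpop_parse_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          na.strings = missing, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genotype_table(df)
}

#' @rdname read_genotypes
#' @param x A `genotype_table`.
#' @export
write_genotypes <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "genotype_table"))
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
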