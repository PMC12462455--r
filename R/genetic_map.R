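#' Default autosomal genetic map
#'
#' A sex-averaged table of genetic lengths for the 22 human autosomes,
#' totalling about 3546 cM. Used by the pedigree simulator and by the
#' synthetic cohort generator to place segments on chromosomes.
#'
#' @return A data frame with columns `chrom` (integer 1-22) and
#'   `length_cM` (numeric, > 0).
#' @export
#' @examples
#' m <- default_genetic_map()
#' sum(m$length_cM)
default_genetic_map <- function() {
  data.frame(
    chrom = 1:22,
    length_cM = c(286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0,
                  166.4, 181.1, 158.2, 174.7, 125.7, 120.2, 141.9, 134.0,
                  128.5, 117.7, 107.9, 108.3, 62.8, 74.1)
  )
}

#' Read a genetic map from a TSV file
#'
#' Expects columns `chrom` and `length_cM`; optional columns
#' `length_female_cM` and `length_male_cM` are averaged into `length_cM`
#' when `length_cM` itself is absent.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame with columns `chrom` and `length_cM`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"chrom" %in% names(df)) {
    stop("genetic map is missing column 'chrom'")
  }
  if (!"length_cM" %in% names(df)) {
    if (all(c("length_female_cM", "length_male_cM") %in% names(df))) {
      df$length_cM <- (df$length_female_cM + df$length_male_cM) / 2
    } else {
      stop("genetic map is missing column 'length_cM'")
    }
  }
  validate_genetic_map(df[, c("chrom", "length_cM")])
}

validate_genetic_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("chrom", "length_cM") %in% names(map)))
  if (any(map$length_cM <= 0)) stop("genetic map lengths must be > 0")
  if (anyDuplicated(map$chrom)) stop("duplicated chromosome in genetic map")
  map
}
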