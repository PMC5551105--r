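#' Read a GENEPOP genotype file
#'
#' Parses diploid GENEPOP files in the 2- or 3-digit allele dialect
#' (auto-detected from the genotype string width). Missing genotypes
#' (`0000` / `000000`) become `NA`. Population blocks are delimited by `Pop`
#' lines; each population is named after the identifier of its first
#' individual (with any trailing index stripped of nothing -- the label is
#' taken verbatim), the convention used by [write_genepop()].
#'
#' @param path Path to a GENEPOP file.
#' @return A tidy genotype tibble (`population`, `individual`, `locus`,
#'   `allele_1`, `allele_2`), the format used throughout the package.
#' @seealso [write_genepop()]
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GENEPOP file: too few lines", call. = FALSE)
  body <- lines[-1] # first line is the title
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) {
    stop("not a GENEPOP file: no 'Pop' separator found", call. = FALSE)
  }
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  # loci may be one per line or comma-separated on one line
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]

  blocks <- split(
    seq_along(body)[-seq_len(pop_idx[1])],
    findInterval(seq_along(body)[-seq_len(pop_idx[1])], pop_idx)
  )
  out <- purrr::imap(blocks, function(rows, bi) {
    rows <- rows[!(rows %in% pop_idx)]
    if (length(rows) == 0) return(NULL)
    recs <- purrr::map(body[rows], function(line) {
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2) {
        stop("malformed GENEPOP individual line: ", line, call. = FALSE)
      }
      id <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                        "\\s+")[[1]]
      if (length(genos) != length(loci)) {
        stop("individual '", id, "' has ", length(genos),
             " genotypes for ", length(loci), " loci", call. = FALSE)
      }
      width <- unique(nchar(genos))
      if (!all(width %in% c(4L, 6L))) {
        stop("genotype strings must be 4 or 6 characters, got width(s) ",
             paste(width, collapse = ", "), " for individual '", id, "'",
             call. = FALSE)
      }
      half <- width[1] / 2
      a1 <- as.integer(substr(genos, 1, half))
      a2 <- as.integer(substr(genos, half + 1, 2 * half))
      a1[a1 == 0] <- NA_integer_
      a2[a2 == 0] <- NA_integer_
      both_na <- is.na(a1) & is.na(a2)
      tibble::tibble(individual_label = id, locus = loci,
                     allele_1 = ifelse(both_na, NA_integer_, pmin(a1, a2)),
                     allele_2 = ifelse(both_na, NA_integer_, pmax(a1, a2)))
    })
    pop_name <- recs[[1]]$individual_label[1]
    dplyr::bind_rows(
      purrr::imap(recs, function(r, i) {
        r$population <- pop_name
        r$individual <- sprintf("%s_%03d", pop_name, as.integer(i))
        r[c("population", "individual", "locus", "allele_1", "allele_2")]
      })
    )
  })
  geno <- dplyr::bind_rows(out)
  check_genotype_table(geno)
  geno
}

#' Write a genotype table as a GENEPOP file
#'
#' Writes the tidy genotype table in the 3-digit (default) or 2-digit
#' GENEPOP dialect. Missing genotypes are written as zeros. Each
#' individual's identifier is the population label, so [read_genepop()]
#' recovers population names exactly.
#'
#' @inheritParams heterozygosity_table
#' @param path Output path.
#' @param digits Allele-code width, 2 or 3.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, digits = 3,
                          title = "locustload genotype export") {
  check_genotype_table(geno)
  if (!digits %in% c(2, 3)) stop("`digits` must be 2 or 3", call. = FALSE)
  max_code <- suppressWarnings(max(geno$allele_1, geno$allele_2, na.rm = TRUE))
  if (is.finite(max_code) && max_code >= 10^digits) {
    stop("allele code ", max_code, " does not fit in ", digits, " digits",
         call. = FALSE)
  }
  loci <- unique(geno$locus)
  fmt <- function(a) sprintf(paste0("%0", digits, "d"),
                             ifelse(is.na(a), 0L, a))
  lines <- c(title, loci)
  for (pop in unique(geno$population)) {
    lines <- c(lines, "Pop")
    sub <- geno[geno$population == pop, ]
    for (ind in unique(sub$individual)) {
      d <- sub[sub$individual == ind, ]
      d <- d[match(loci, d$locus), ]
      lines <- c(lines,
                 paste0(pop, " ,  ",
                        paste0(fmt(d$allele_1), fmt(d$allele_2),
                               collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
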