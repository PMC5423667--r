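#' Diploid microsatellite genotype tables
#'
#' A `genotype_tbl` is a long-format tibble holding diploid microsatellite
#' calls: one row per individual per locus, with the two allele labels given
#' as integer fragment sizes in base pairs. Missing genotypes carry `NA` in
#' both allele columns; half-calls (one allele present, one absent) are not a
#' valid state and are coerced to missing on construction.
#'
#' Population and locus order is the order of first appearance in the input,
#' preserved as factor levels; every report downstream keeps that order.
#'
#' @param x A data frame with columns `individual`, `population`, `locus`,
#'   `allele_1`, `allele_2`. Allele columns must be positive integers or `NA`.
#' @return A tibble of class `genotype_tbl`.
#' @examples
#' gt <- genotype_table(tibble::tibble(
#'   individual = c("i1", "i2"), population = "A", locus = "L1",
#'   allele_1 = c(100L, 100L), allele_2 = c(120L, 100L)
#' ))
#' allele_frequencies(gt)
#' @export
genotype_table <- function(x) {
  required <- c("individual", "population", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("genotype table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)[required]
  x$individual <- as.character(x$individual)
  x$allele_1 <- suppressWarnings(as.integer(x$allele_1))
  x$allele_2 <- suppressWarnings(as.integer(x$allele_2))
  # allele label 0 is the missing convention in several exchange formats
  x$allele_1[!is.na(x$allele_1) & x$allele_1 <= 0] <- NA_integer_
  x$allele_2[!is.na(x$allele_2) & x$allele_2 <= 0] <- NA_integer_

  half <- xor(is.na(x$allele_1), is.na(x$allele_2))
  if (any(half)) {
    warning(sum(half), " half-called genotype(s) coerced to missing",
            call. = FALSE)
    x$allele_1[half] <- NA_integer_
    x$allele_2[half] <- NA_integer_
  }

  x$population <- factor(as.character(x$population),
                         levels = unique(as.character(x$population)))
  x$locus <- factor(as.character(x$locus),
                    levels = unique(as.character(x$locus)))

  pop_per_ind <- tapply(as.character(x$population), x$individual,
                        function(p) length(unique(p)))
  if (any(pop_per_ind > 1)) {
    stop("individual(s) assigned to more than one population: ",
         paste(names(pop_per_ind)[pop_per_ind > 1], collapse = ", "),
         call. = FALSE)
  }

  n_loci <- tapply(as.character(x$locus), x$individual,
                   function(l) length(unique(l)))
  if (length(unique(n_loci)) > 1) {
    stop("inconsistent locus count across individuals", call. = FALSE)
  }

  class(x) <- c("genotype_tbl", class(tibble::tibble()))
  x
}

#' @export
print.genotype_tbl <- function(x, ...) {
  cat("# Genotype table: ", length(unique(x$individual)), " individuals, ",
      nlevels(x$population), " populations, ", nlevels(x$locus), " loci\n",
      sep = "")
  NextMethod()
}

#' @rdname genotype_table
#' @export
is_genotype_tbl <- function(x) inherits(x, "genotype_tbl")

pop_levels <- function(gt) levels(gt$population)
locus_levels <- function(gt) levels(gt$locus)

#' Read a GenePop file
#'
#' Parses the GenePop exchange dialect: a title line, locus names (one per
#' line or a single comma-separated line), `POP` separators, and individual
#' lines `id , a1a2 a1a2 ...` with 2- or 3-digit allele encoding. The code
#' `00`/`000` (so `0000` or `000000` per genotype) marks a missing genotype.
#'
#' @param path Path to a GenePop (.gen) file.
#' @param pop_names `"last_id"` names each population after the ID of the
#'   last individual in its POP block (the common convention); `"auto"`
#'   names them `POP1`..`POPk`.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, pop_names = c("last_id", "auto")) {
  pop_names <- match.arg(pop_names)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GenePop file: fewer than 3 lines")

  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GenePop file: no POP separator found")

  header <- lines[2:(first_pop - 1)]
  loci <- unlist(strsplit(header, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]

  blocks <- split(
    seq_along(lines)[-seq_len(first_pop - 1)],
    cumsum(is_pop)[-seq_len(first_pop - 1)]
  )

  rows <- list()
  pop_labels <- character(0)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    idx <- idx[!is_pop[idx]]
    if (length(idx) == 0) next
    block_rows <- lapply(idx, function(i) {
      parts <- strsplit(lines[i], ",")[[1]]
      if (length(parts) < 2) {
        stop("malformed GenePop line ", i, ": no comma separator",
             call. = FALSE)
      }
      id <- trimws(parts[1])
      fields <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                         "\\s+")[[1]]
      if (length(fields) != length(loci)) {
        stop("malformed GenePop line ", i, ": ", length(fields),
             " genotype field(s) for ", length(loci), " loci", call. = FALSE)
      }
      width <- unique(nchar(fields))
      if (length(width) != 1 || !width %in% c(4L, 6L)) {
        stop("malformed GenePop line ", i,
             ": genotype fields must be 4 or 6 digits", call. = FALSE)
      }
      half <- width / 2
      a1 <- as.integer(substr(fields, 1, half))
      a2 <- as.integer(substr(fields, half + 1, width))
      tibble::tibble(individual = id, locus = loci,
                     allele_1 = a1, allele_2 = a2)
    })
    block <- dplyr::bind_rows(block_rows)
    label <- if (pop_names == "last_id") {
      utils::tail(unique(block$individual), 1)
    } else {
      paste0("POP", b)
    }
    block$population <- label
    pop_labels <- c(pop_labels, label)
    rows[[b]] <- block
  }
  out <- dplyr::bind_rows(rows)
  genotype_table(out[c("individual", "population", "locus",
                       "allele_1", "allele_2")])
}

#' Write a GenePop file
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @param title Title line.
#' @param digits Allele encoding width per allele, 2 or 3 (default 3, which
#'   accommodates raw fragment sizes up to 999 bp).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "skagerrak genotype export",
                          digits = 3) {
  stopifnot(is_genotype_tbl(gt), digits %in% c(2, 3))
  if (max(c(gt$allele_1, gt$allele_2), na.rm = TRUE) >= 10^digits) {
    stop("allele labels do not fit in ", digits, "-digit encoding")
  }
  enc <- function(a) {
    out <- formatC(ifelse(is.na(a), 0L, a), width = digits, flag = "0")
    out
  }
  wide <- gt |>
    dplyr::mutate(field = paste0(enc(.data$allele_1), enc(.data$allele_2))) |>
    dplyr::select("individual", "population", "locus", "field") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "field")

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(locus_levels(gt), con)
  for (pop in pop_levels(gt)) {
    writeLines("POP", con)
    sub <- wide[wide$population == pop, ]
    writeLines(paste0(sub$individual, " , ",
                      apply(sub[, -(1:2), drop = FALSE], 1, paste,
                            collapse = " ")), con)
  }
  invisible(path)
}

#' Read a delimited genotype table
#'
#' Reads the two-columns-per-locus layout used by spreadsheet exports of
#' microsatellite scores: an individual column, a population column, then
#' two adjacent columns per locus holding the two allele calls. Blank, `0`
#' and `NA` cells mark missing alleles. Locus names are taken from the first
#' column of each pair, stripping a trailing `_1`/`.1`/`a` style suffix when
#' the pair is named that way.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension, comma otherwise).
#' @param delim Optional explicit delimiter.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), name_repair = "minimal", progress = FALSE)
  hdr <- names(raw)
  if (ncol(raw) < 4 || (ncol(raw) - 2) %% 2 != 0) {
    stop("unrecognised genotype table layout; detected headers: ",
         paste(hdr, collapse = ", "), call. = FALSE)
  }
  locus_cols <- hdr[-(1:2)]
  first_of_pair <- locus_cols[seq(1, length(locus_cols), by = 2)]
  loci <- sub("([._ -]?(1|a|A))$", "", first_of_pair)

  n_loci <- length(loci)
  pieces <- lapply(seq_len(n_loci), function(j) {
    a1 <- raw[[2 + 2 * j - 1]]
    a2 <- raw[[2 + 2 * j]]
    tibble::tibble(
      individual = as.character(raw[[1]]),
      population = as.character(raw[[2]]),
      locus = loci[j],
      allele_1 = suppressWarnings(as.integer(a1)),
      allele_2 = suppressWarnings(as.integer(a2))
    )
  })
  long <- dplyr::bind_rows(pieces)
  # restore input row order within the long layout: individuals as they appear
  long$individual <- factor(long$individual, levels = unique(as.character(raw[[1]])))
  long <- dplyr::arrange(long, .data$individual, factor(.data$locus, levels = loci))
  long$individual <- as.character(long$individual)
  genotype_table(long)
}

#' Write a delimited genotype table
#'
#' Inverse of [read_genotype_table()]: two columns per locus, named
#' `<locus>_1` and `<locus>_2`; missing genotypes written as empty cells.
#'
#' @param gt A [genotype_table()].
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  stopifnot(is_genotype_tbl(gt))
  wide <- gt |>
    dplyr::mutate(locus = as.character(.data$locus)) |>
    tidyr::pivot_wider(names_from = "locus",
                       values_from = c("allele_1", "allele_2"),
                       names_glue = "{locus}_{.value}")
  # interleave so each locus's two columns are adjacent
  loci <- locus_levels(gt)
  ordered_cols <- c("individual", "population",
                    as.vector(rbind(paste0(loci, "_allele_1"),
                                    paste0(loci, "_allele_2"))))
  names(ordered_cols) <- NULL
  wide <- wide[, ordered_cols]
  names(wide) <- c("individual", "population",
                   as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Per-population allele frequencies
#'
#' Tallies allele copies among non-missing calls for every
#' (population, locus) combination and normalises to frequencies. The
#' gene-copy count `n` is twice the number of non-missing individuals, so
#' missing data shrinks `n` per locus. A population with no calls at a locus
#' yields no allele rows but is still represented in [gene_copies()] with
#' `n = 0`; downstream statistics treat that case as undefined.
#'
#' @param gt A [genotype_table()].
#' @return A tibble of class `allele_freq_tbl` with columns `population`,
#'   `locus`, `allele`, `count`, `freq`, `n`.
#' @export
allele_frequencies <- function(gt) {
  stopifnot(is_genotype_tbl(gt))
  long <- gt |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::count(.data$population, .data$locus, .data$allele,
                 name = "count") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(n = sum(.data$count), freq = .data$count / .data$n) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$population, .data$locus, .data$allele) |>
    dplyr::select("population", "locus", "allele", "count", "freq", "n")
  class(long) <- c("allele_freq_tbl", class(tibble::tibble()))
  long
}

#' Gene-copy counts per population and locus
#'
#' @param gt A [genotype_table()].
#' @return A tibble with `population`, `locus`, `n_ind` (non-missing
#'   individuals) and `n` (gene copies, `2 * n_ind`); zero where a
#'   population is entirely untyped at a locus.
#' @export
gene_copies <- function(gt) {
  stopifnot(is_genotype_tbl(gt))
  gt |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(n_ind = sum(!is.na(.data$allele_1)),
                     n = 2L * .data$n_ind, .groups = "drop") |>
    tidyr::complete(.data$population, .data$locus,
                    fill = list(n_ind = 0L, n = 0L))
}
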