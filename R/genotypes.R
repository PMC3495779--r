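#' @useDynLib pollenkin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx cor cor.test dgamma dlnorm density integrate
#'   ks.test optim optimize quantile rbeta rbinom rgamma rlnorm rnorm
#'   runif sd setNames t.test var
#' @importFrom graphics abline arrows barplot hist legend lines par points
#'   polygon segments
#' @importFrom grDevices grey
#' @importFrom utils head modifyList read.csv write.csv
NULL

# ---- internal genotype helpers ------------------------------------------

## genotypes live in a character array n x 2 x L; NA for missing; a
## locus-genotype is all-or-nothing (half calls rejected at parse time)

.sort_alleles <- function(a) {
  a <- unique(a[!is.na(a)])
  if (length(a) && !anyNA(suppressWarnings(as.numeric(a)))) {
    a[order(as.numeric(a))]
  } else {
    sort(a)
  }
}

.build_loci <- function(geno, extra = NULL) {
  ln <- dimnames(geno)[[3]]
  out <- lapply(seq_along(ln), function(l) {
    obs <- c(geno[, , l], if (!is.null(extra)) extra[[ln[l]]])
    .sort_alleles(obs)
  })
  names(out) <- ln
  out
}

.check_geno_array <- function(geno, what = "genotype") {
  if (length(dim(geno)) != 3L || dim(geno)[2] != 2L)
    stop("genotype array must have dimensions n x 2 x n_loci")
  half <- is.na(geno[, 1, , drop = FALSE]) != is.na(geno[, 2, , drop = FALSE])
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)
    stop(sprintf(
      "single-allele %s record for individual %s at locus %s (alleles are all-or-nothing per locus)",
      what, dimnames(geno)[[1]][idx[1, 1]], dimnames(geno)[[3]][idx[1, 3]]))
  }
  invisible(geno)
}

## parse "a/b" tokens from a data.frame block of locus columns
.parse_geno_columns <- function(df, locus_cols, ids, file = "<data>") {
  n <- nrow(df)
  geno <- array(NA_character_, dim = c(n, 2L, length(locus_cols)),
                dimnames = list(ids, NULL, locus_cols))
  for (l in seq_along(locus_cols)) {
    tok <- trimws(as.character(df[[locus_cols[l]]]))
    tok[tok == "" | is.na(tok)] <- "NA/NA"
    parts <- strsplit(tok, "/", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop(sprintf("malformed genotype token '%s' at line %d, locus %s of %s",
                   tok[bad[1]], bad[1] + 1L, locus_cols[l], file))
    m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
    m[m == "NA" | m == "na" | m == "0" | m == "?"] <- NA_character_
    half <- xor(is.na(m[, 1]), is.na(m[, 2]))
    if (any(half))
      stop(sprintf("single-allele genotype '%s' at line %d, locus %s of %s",
                   tok[which(half)[1]], which(half)[1] + 1L, locus_cols[l], file))
    geno[, , l] <- m
  }
  geno
}

.geno_tokens <- function(geno) {
  ## inverse of .parse_geno_columns: n x L matrix of "a/b" strings
  n <- dim(geno)[1]; L <- dim(geno)[3]
  out <- matrix("NA/NA", n, L, dimnames = dimnames(geno)[c(1, 3)])
  for (l in seq_len(L)) {
    a <- geno[, 1, l]; b <- geno[, 2, l]
    ok <- !is.na(a)
    out[ok, l] <- paste(a[ok], b[ok], sep = "/")
  }
  out
}

# ---- spatial genotype tables --------------------------------------------

#' Spatially mapped adult genotype table
#'
#' Container for the adult census used throughout the package: one row per
#' individual with its sex, planar coordinates in metres, an optional
#' habitat class, and a diploid multilocus genotype.
#'
#' @param ind data.frame with columns `id`, `sex` (`"male"`/`"female"`),
#'   `x`, `y` (metres, local planar frame) and optionally `habitat`.
#' @param geno character array `n x 2 x n_loci` of allele labels (third
#'   dimension named by locus), `NA` for missing; a locus-genotype must be
#'   fully typed or fully missing.
#'
#' @return An object of class `spatial_genotypes`: a list with elements
#'   `ind` (the individual table), `geno` (the genotype array) and `loci`
#'   (named list of allele catalogues per locus).
#' @export
spatial_genotypes <- function(ind, geno) {
  stopifnot(is.data.frame(ind),
            all(c("id", "sex", "x", "y") %in% names(ind)))
  ind$id <- as.character(ind$id)
  if (anyDuplicated(ind$id))
    stop("duplicate individual id: ", ind$id[duplicated(ind$id)][1])
  if (!all(ind$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(is.finite(ind$x)) || !all(is.finite(ind$y)))
    stop("coordinates must be finite")
  if (is.null(ind$habitat)) ind$habitat <- NA_character_
  .check_geno_array(geno)
  if (dim(geno)[1] != nrow(ind))
    stop("genotype array and individual table disagree in size")
  dimnames(geno)[[1]] <- ind$id
  structure(list(ind = ind, geno = geno, loci = .build_loci(geno)),
            class = "spatial_genotypes")
}

#' @export
print.spatial_genotypes <- function(x, ...) {
  ns <- table(factor(x$ind$sex, c("male", "female")))
  miss <- mean(is.na(x$geno[, 1, , drop = FALSE]))
  cat(sprintf(
    "Spatial genotype table: %d individuals (%d males, %d females), %d loci, %.1f%% missing\n",
    nrow(x$ind), ns[["male"]], ns[["female"]], dim(x$geno)[3], 100 * miss))
  cat(sprintf("Extent: x %.0f-%.0f m, y %.0f-%.0f m\n",
              min(x$ind$x), max(x$ind$x), min(x$ind$y), max(x$ind$y)))
  invisible(x)
}

#' Read a spatially mapped adult table
#'
#' The native format is CSV with columns `id`, `sex`, `x`, `y`, optionally
#' `habitat`, and one column per locus holding `"a/b"` allele pairs
#' (`"NA/NA"` for missing). A GenePop-dialect reader is available for
#' interoperability; it takes the genotypes from a GenePop file and the
#' coordinates from a companion CSV.
#'
#' @param path path to the CSV file (or GenePop file when
#'   `format = "genepop"`).
#' @param format `"csv"` or `"genepop"`.
#' @param coords for `format = "genepop"`, path to a CSV with columns
#'   `id`, `sex`, `x`, `y` and optionally `habitat`.
#' @param quiet suppress the parse report.
#' @return A [spatial_genotypes] object.
#' @export
read_adults <- function(path, format = c("csv", "genepop"), coords = NULL,
                        quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genepop") return(read_genepop(path, coords, quiet = quiet))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- intersect(c("id", "sex", "x", "y", "habitat"), names(df))
  locus_cols <- setdiff(names(df), fixed)
  if (!length(locus_cols)) stop("no locus columns found in ", path)
  geno <- .parse_geno_columns(df, locus_cols, as.character(df$id), path)
  x <- spatial_genotypes(df[fixed], geno)
  if (!quiet)
    message(sprintf("read %d individuals, %d loci, %.1f%% missing from %s",
                    nrow(x$ind), length(locus_cols),
                    100 * mean(is.na(geno[, 1, , drop = FALSE])), path))
  x
}

#' Write a spatially mapped adult table to CSV
#'
#' @param x a [spatial_genotypes] object.
#' @param path output CSV path.
#' @export
write_adults <- function(x, path) {
  stopifnot(inherits(x, "spatial_genotypes"))
  df <- cbind(x$ind[c("id", "sex", "x", "y", "habitat")],
              as.data.frame(.geno_tokens(x$geno), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes in GenePop format with companion coordinates
#'
#' Parses a single-population GenePop file (2- or 3-digit diploid allele
#' codes, `00`/`000` for missing) and joins coordinates, sex and habitat
#' from a CSV keyed by individual id.
#'
#' @inheritParams read_adults
#' @return A [spatial_genotypes] object.
#' @export
read_genepop <- function(path, coords, quiet = FALSE) {
  if (is.null(coords)) stop("GenePop input needs a coordinate CSV (coords=)")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_at <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)[1]
  if (is.na(pop_at)) stop("no 'Pop' line in GenePop file ", path)
  header <- lines[2:(pop_at - 1)]
  loci <- trimws(unlist(strsplit(paste(header, collapse = ","), ",")))
  loci <- loci[nzchar(loci)]
  rows <- lines[(pop_at + 1):length(lines)]
  parts <- strsplit(rows, ",")
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  genostr <- trimws(vapply(parts, function(p) paste(p[-1], collapse = " "), ""))
  toks <- strsplit(genostr, "\\s+")
  if (any(lengths(toks) != length(loci)))
    stop("GenePop row with wrong number of locus fields in ", path)
  n <- length(ids)
  geno <- array(NA_character_, c(n, 2L, length(loci)),
                dimnames = list(ids, NULL, loci))
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    w <- nchar(tk) / 2L
    if (any(w != floor(w)) || any(!w %in% c(2L, 3L)))
      stop(sprintf("malformed GenePop genotype '%s' for individual %s",
                   tk[which(!(nchar(tk) %in% c(4L, 6L)))[1]], ids[i]))
    a1 <- substr(tk, 1L, w)
    a2 <- substr(tk, w + 1L, 2L * w)
    a1[as.integer(a1) == 0L] <- NA
    a2[as.integer(a2) == 0L] <- NA
    if (any(xor(is.na(a1), is.na(a2))))
      stop("single-allele GenePop genotype for individual ", ids[i])
    keep <- !is.na(a1)
    a1[keep] <- as.character(as.integer(a1[keep]))
    a2[keep] <- as.character(as.integer(a2[keep]))
    geno[i, 1, ] <- a1
    geno[i, 2, ] <- a2
  }
  cc <- read.csv(coords, stringsAsFactors = FALSE)
  m <- match(ids, as.character(cc$id))
  if (anyNA(m))
    stop("no coordinates for individuals: ",
         paste(head(ids[is.na(m)]), collapse = ", "))
  ind <- cc[m, intersect(c("id", "sex", "x", "y", "habitat"), names(cc))]
  x <- spatial_genotypes(ind, geno)
  if (!quiet)
    message(sprintf("read %d individuals, %d loci from GenePop %s",
                    n, length(loci), path))
  x
}

# ---- progeny arrays ------------------------------------------------------

#' Progeny array: seeds grouped by mother
#'
#' @param seeds data.frame with columns `seed_id` and `mother_id`.
#' @param geno character array `n_seeds x 2 x n_loci` of allele labels.
#' @param adults optional [spatial_genotypes] table against which mother
#'   ids are validated (they must be genotyped females).
#' @param min_loci seeds typed at fewer loci are flagged (`keep = FALSE`)
#'   and excluded by downstream analyses; default 5.
#'
#' @return An object of class `progeny_array`: list with `seeds` (the seed
#'   table, including an `n_loci` count and `keep` flag), `geno` and
#'   `loci`.
#' @export
progeny_array <- function(seeds, geno, adults = NULL, min_loci = 5L) {
  stopifnot(is.data.frame(seeds),
            all(c("seed_id", "mother_id") %in% names(seeds)))
  seeds$seed_id <- as.character(seeds$seed_id)
  seeds$mother_id <- as.character(seeds$mother_id)
  if (anyDuplicated(seeds$seed_id))
    stop("duplicate seed id: ", seeds$seed_id[duplicated(seeds$seed_id)][1])
  .check_geno_array(geno, "seed")
  if (dim(geno)[1] != nrow(seeds))
    stop("genotype array and seed table disagree in size")
  dimnames(geno)[[1]] <- seeds$seed_id
  if (!is.null(adults)) {
    mothers <- adults$ind$id[adults$ind$sex == "female"]
    orphan <- setdiff(unique(seeds$mother_id), mothers)
    if (length(orphan))
      stop("mother ids absent from the adult table (females): ",
           paste(orphan, collapse = ", "))
  }
  seeds$n_loci <- as.integer(rowSums(!is.na(geno[, 1, , drop = FALSE])))
  seeds$keep <- seeds$n_loci >= min_loci
  structure(list(seeds = seeds, geno = geno, loci = .build_loci(geno),
                 min_loci = as.integer(min_loci)),
            class = "progeny_array")
}

#' @export
print.progeny_array <- function(x, ...) {
  fam <- table(x$seeds$mother_id)
  cat(sprintf(
    "Progeny array: %d seeds from %d mothers (mean %.1f seeds/mother), %d loci\n",
    nrow(x$seeds), length(fam), mean(fam), dim(x$geno)[3]))
  if (any(!x$seeds$keep))
    cat(sprintf("%d seeds typed at < %d loci are flagged for exclusion\n",
                sum(!x$seeds$keep), x$min_loci))
  invisible(x)
}

#' Read a progeny array from CSV
#'
#' Expects columns `seed_id`, `mother_id` and one `"a/b"` column per
#' locus. Mother ids are checked against the genotyped females of
#' `adults`. Seeds typed at fewer than `min_loci` loci are flagged and
#' excluded from downstream analyses.
#'
#' @param path CSV path.
#' @param adults [spatial_genotypes] table containing the mothers.
#' @param min_loci minimum number of typed loci per seed (default 5).
#' @param quiet suppress the parse report.
#' @return A [progeny_array].
#' @export
read_progeny <- function(path, adults = NULL, min_loci = 5L, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    warning("empty progeny file: ", path)
    L <- setdiff(names(df), c("seed_id", "mother_id"))
    geno <- array(NA_character_, c(0L, 2L, length(L)),
                  dimnames = list(NULL, NULL, L))
    return(progeny_array(data.frame(seed_id = character(),
                                    mother_id = character()),
                         geno, adults, min_loci))
  }
  locus_cols <- setdiff(names(df), c("seed_id", "mother_id"))
  geno <- .parse_geno_columns(df, locus_cols, as.character(df$seed_id), path)
  x <- progeny_array(df[c("seed_id", "mother_id")], geno, adults, min_loci)
  if (!quiet)
    message(sprintf("read %d seeds from %d mothers, %d loci from %s",
                    nrow(x$seeds), length(unique(x$seeds$mother_id)),
                    length(locus_cols), path))
  x
}

#' Write a progeny array to CSV
#' @param x a [progeny_array].
#' @param path output CSV path.
#' @export
write_progeny <- function(x, path) {
  stopifnot(inherits(x, "progeny_array"))
  df <- cbind(x$seeds[c("seed_id", "mother_id")],
              as.data.frame(.geno_tokens(x$geno), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- shared internal utilities ------------------------------------------

## integer-coded view of a genotype array against a locus catalogue
.codes <- function(geno, catalog) {
  L <- dim(geno)[3]
  out <- vector("list", L)
  for (l in seq_len(L)) {
    cat_l <- catalog[[dimnames(geno)[[3]][l]]]
    m <- matrix(match(geno[, , l], cat_l), ncol = 2L)
    out[[l]] <- m
  }
  names(out) <- dimnames(geno)[[3]]
  out
}

## union allele catalogue across tables / frequency sets
.union_catalog <- function(...) {
  parts <- list(...)
  ln <- unique(unlist(lapply(parts, function(p) names(p))))
  out <- lapply(ln, function(nm) {
    .sort_alleles(unlist(lapply(parts, function(p) p[[nm]])))
  })
  names(out) <- ln
  out
}

.pairwise_dist <- function(xy1, xy2 = xy1) {
  dx <- outer(xy1[, 1], xy2[, 1], "-")
  dy <- outer(xy1[, 2], xy2[, 2], "-")
  sqrt(dx^2 + dy^2)
}

#' Azimuth of the vector between two points
#'
#' Bearings are measured package-wide in degrees clockwise from north.
#' For a mating event the bearing is taken from the father (pollen
#' source) to the mother, matching wind-rose semantics.
#'
#' @param from,to two-column matrices (or length-2 vectors) of x/y
#'   coordinates in metres.
#' @return Azimuths in `[0, 360)` degrees.
#' @export
bearing_deg <- function(from, to) {
  if (is.null(dim(from))) from <- matrix(from, ncol = 2)
  if (is.null(dim(to))) to <- matrix(to, ncol = 2)
  dx <- to[, 1] - from[, 1]
  dy <- to[, 2] - from[, 2]
  (atan2(dx, dy) * 180 / pi) %% 360
}
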