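#' Read a LINKAGE-style (pre-makeped) pedigree file
#'
#' Whitespace-delimited, one individual per line:
#' `FamID IndID FatherID MotherID Sex Phenotype Allele1 Allele2 ...`
#' with two allele columns per marker, integer allele codes and 0 as the
#' missing code. Sex is coded 1 = male, 2 = female, 0 = unknown. The single
#' phenotype placeholder column is ignored; quantitative phenotypes travel in
#' a separate CSV (see [read_phenotypes()]).
#'
#' @param path Path to the .ped file.
#' @return An object of class `edsp_ped`: list with `individuals` (data.frame
#'   family_id, individual_id, father_id, mother_id, sex), `genotypes`
#'   (integer matrix, two columns per marker) and `n_markers`.
#' @seealso [write_ped()]
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("ped file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(list(
      individuals = data.frame(family_id = character(), individual_id = character(),
                               father_id = character(), mother_id = character(),
                               sex = integer(), stringsAsFactors = FALSE),
      genotypes = matrix(integer(), 0L, 0L), n_markers = 0L),
      class = "edsp_ped"))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (length(unique(len)) != 1L) {
    stop("ped format error: lines have differing column counts")
  }
  if (len[1L] < 6L || (len[1L] - 6L) %% 2L != 0L) {
    stop("ped format error: expected 6 leading columns plus an even number of allele columns")
  }
  mat <- do.call(rbind, toks)
  key <- paste(mat[, 1L], mat[, 2L])
  if (anyDuplicated(key)) {
    stop("ped format error: duplicate (family, individual) id: ",
         key[duplicated(key)][1L])
  }
  sex <- suppressWarnings(as.integer(mat[, 5L]))
  if (any(is.na(sex)) || !all(sex %in% 0:2)) {
    stop("ped format error: sex must be coded 0/1/2")
  }
  n_markers <- (len[1L] - 6L) %/% 2L
  geno <- matrix(integer(), nrow(mat), 0L)
  if (n_markers > 0L) {
    raw <- mat[, -(1:6), drop = FALSE]
    g <- suppressWarnings(as.integer(raw))
    if (any(is.na(g)) || any(g != suppressWarnings(as.numeric(raw)), na.rm = TRUE)) {
      stop("ped format error: non-integer allele code")
    }
    if (any(g < 0L)) stop("ped format error: negative allele code")
    geno <- matrix(g, nrow(mat), 2L * n_markers)
  }
  structure(list(
    individuals = data.frame(family_id = mat[, 1L], individual_id = mat[, 2L],
                             father_id = mat[, 3L], mother_id = mat[, 4L],
                             sex = sex, stringsAsFactors = FALSE),
    genotypes = geno, n_markers = n_markers),
    class = "edsp_ped")
}

#' Write a LINKAGE-style (pre-makeped) pedigree file
#'
#' Inverse of [read_ped()]. Allele pairs are written smaller-first so output
#' is deterministic; missing genotypes appear as `0 0` and the phenotype
#' placeholder column as `0`. Accepts an `edsp_ped` or a simulated
#' [simulate_families()] cohort.
#'
#' @param x An `edsp_ped` or `edsp_cohort`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(x, path) {
  ind <- x$individuals
  G <- x$genotypes
  n <- nrow(ind)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write ped file: ", conditionMessage(e)))
  on.exit(close(con))
  if (n == 0L) return(invisible(path))
  m <- ncol(G) %/% 2L
  if (m > 0L) {
    for (j in seq_len(m)) {   # sort each allele pair ascending
      a <- G[, 2L * j - 1L]; b <- G[, 2L * j]
      G[, 2L * j - 1L] <- pmin(a, b)
      G[, 2L * j] <- pmax(a, b)
    }
  }
  lines <- paste(ind$family_id, ind$individual_id, ind$father_id,
                 ind$mother_id, ind$sex, 0L)
  if (m > 0L) {
    lines <- paste(lines, apply(G, 1L, paste, collapse = " "))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a marker map table
#'
#' Tab-separated with a header; required columns `name` and `chromosome`,
#' optional `theta`, `n_alleles` (default 8), `freqs` (comma-separated allele
#' frequencies) and `range_bp`. Column order of genotype files must follow
#' the map order.
#'
#' @param path Path to the TSV.
#' @return A list of [marker_def()] objects.
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) stop("marker map not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chromosome")
  if (!all(need %in% names(tab))) {
    stop("marker map format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (anyDuplicated(tab$name)) stop("marker map format error: duplicate marker names")
  lapply(seq_len(nrow(tab)), function(i) {
    n_all <- if ("n_alleles" %in% names(tab)) as.integer(tab$n_alleles[i]) else 8L
    freqs <- if ("freqs" %in% names(tab) && nzchar(tab$freqs[i]) &&
                 !is.na(tab$freqs[i])) {
      as.numeric(strsplit(tab$freqs[i], ",")[[1L]])
    } else rep(1 / n_all, n_all)
    if (length(freqs) != n_all) {
      stop("marker map format error: `freqs` length differs from `n_alleles` for ",
           tab$name[i])
    }
    marker_def(tab$name[i], n_alleles = n_all, allele_freqs = freqs,
               theta = if ("theta" %in% names(tab)) as.numeric(tab$theta[i]) else NA_real_,
               chromosome = as.character(tab$chromosome[i]),
               bp_range = if ("range_bp" %in% names(tab)) as.character(tab$range_bp[i]) else NA_character_)
  })
}

#' Write a marker map table
#'
#' @param markers List of [marker_def()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_map <- function(markers, path) {
  markers <- .check_markers(markers)
  tab <- data.frame(
    name = .marker_names(markers),
    chromosome = vapply(markers, `[[`, character(1), "chromosome"),
    theta = vapply(markers, `[[`, numeric(1), "theta"),
    n_alleles = vapply(markers, `[[`, integer(1), "n_alleles"),
    freqs = vapply(markers, function(m)
      paste(format(m$allele_freqs, digits = 15, trim = TRUE), collapse = ","),
      character(1)),
    range_bp = vapply(markers, `[[`, character(1), "bp_range"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with header; required columns `family_id`, `individual_id`, `sex`,
#' `age`, `sbp`, `dbp`; any further columns (e.g. serum biochemistry) are
#' carried through untouched. Pulse pressure `pp = sbp - dbp` is added;
#' records with `sbp < dbp` are flagged with `pp = NA` and a warning.
#'
#' @param path Path to the CSV.
#' @return A data.frame keyed by (family_id, individual_id).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(family_id = "character",
                                        individual_id = "character"))
  need <- c("family_id", "individual_id", "sex", "age", "sbp", "dbp")
  if (!all(need %in% names(tab))) {
    stop("phenotype format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("no phenotype rows")
  if (anyDuplicated(paste(tab$family_id, tab$individual_id))) {
    stop("phenotype format error: duplicate (family, individual) id")
  }
  tab$pp <- pulse_pressure(tab$sbp, tab$dbp)
  tab
}

#' Write a phenotype table
#'
#' @param pheno Data.frame as returned by [read_phenotypes()] (the derived
#'   `pp` column is dropped on write).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path) {
  pheno$pp <- NULL
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read linkage results tables
#'
#' Results are tab-separated with a header; numeric columns are written at
#' full precision (15 significant digits) so write/read round-trips preserve
#' values to at least 12 significant digits.
#'
#' @param results A data.frame (e.g. an [edsp_scan()] table).
#' @param path Output path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the data.frame.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Join phenotype rows onto pedigree individuals
#'
#' Phenotype rows without a matching pedigree individual are dropped with a
#' warning giving the count.
#'
#' @param ped An `edsp_ped` (or `edsp_cohort`).
#' @param pheno Phenotype data.frame from [read_phenotypes()].
#' @return The pedigree individual table with phenotype columns merged on.
#' @export
attach_phenotypes <- function(ped, pheno) {
  ind <- ped$individuals
  kp <- paste(ind$family_id, ind$individual_id)
  kq <- paste(pheno$family_id, pheno$individual_id)
  drop <- !(kq %in% kp)
  if (any(drop)) {
    warning(sum(drop), " phenotype row(s) without a matching pedigree individual dropped")
    pheno <- pheno[!drop, , drop = FALSE]
  }
  merge(ind, pheno[setdiff(names(pheno), "sex")],
        by = c("family_id", "individual_id"), all.x = TRUE, sort = FALSE)
}
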