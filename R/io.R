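#' Read a labeled numeric matrix from TSV
#'
#' Expects a rectangular tab-separated file with column labels in the header
#' and row labels in the first column. Mixed line endings are accepted.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_expected <- length(header) + 1L  # header lacks the row-label column
  rows <- lapply(seq_along(body), function(i) {
    f <- body[[i]]
    if (length(f) == length(header)) {
      # tolerate a header that already includes the row-label column
      ncol_expected <<- length(header)
    } else if (length(f) != ncol_expected) {
      stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                   i + 1L, path, length(f), ncol_expected), call. = FALSE)
    }
    f
  })
  labels <- vapply(rows, `[[`, character(1), 1L)
  vals <- lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric cell at line %d of %s", i + 1L, path),
           call. = FALSE)
    }
    v
  })
  M <- do.call(rbind, vals)
  colnames(M) <- utils::tail(header, ncol(M))
  rownames(M) <- labels
  M
}

#' Write a labeled numeric matrix as TSV
#'
#' @param M matrix (dimnames generated when absent).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  if (is.null(rownames(M))) rownames(M) <- paste0("r", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("c", seq_len(ncol(M)))
  utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Serialize a community to a directory of TSV files
#'
#' Writes `IM.tsv` (binary backbone), `growth_rates.tsv`, `traits.tsv`, and
#' a `meta.json` sidecar with connectance target and seed.
#'
#' @param community a [make_community()] object.
#' @param path directory to create.
#' @return `path` invisibly (`write`); a `community` object (`read`).
#' @export
write_community <- function(community, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(community$IM, file.path(path, "IM.tsv"))
  gr <- data.frame(
    species = c(rownames(community$IM), colnames(community$IM)),
    guild = rep(c("plant", "animal"), c(community$n_P, community$n_A)),
    growth_rate = c(community$r_P, community$r_A))
  utils::write.table(gr, file.path(path, "growth_rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- data.frame(
    species = gr$species, guild = gr$guild,
    trait = c(community$plant_trait, community$animal_trait))
  utils::write.table(tr, file.path(path, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(phi = community$phi, seed = community$seed,
                            n_P = community$n_P, n_A = community$n_A),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_community
#' @param path directory produced by [write_community()].
#' @export
read_community <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  IM <- read_matrix_tsv(file.path(path, "IM.tsv"))
  gr <- utils::read.delim(file.path(path, "growth_rates.tsv"))
  tr <- utils::read.delim(file.path(path, "traits.tsv"))
  structure(list(
    n_P = as.integer(meta$n_P), n_A = as.integer(meta$n_A), IM = IM,
    plant_trait = tr$trait[tr$guild == "plant"],
    animal_trait = tr$trait[tr$guild == "animal"],
    r_P = gr$growth_rate[gr$guild == "plant"],
    r_A = gr$growth_rate[gr$guild == "animal"],
    phi = meta$phi, seed = as.integer(meta$seed)
  ), class = "community")
}

#' Write an equilibrium result as a JSON record
#'
#' One flat record with final abundances, convergence and stability flags,
#' persistence and steps used; a report format for downstream tooling.
#'
#' @param eq a `glv_equilibrium` (see [integrate_to_equilibrium()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_equilibrium_json <- function(eq, path) {
  jsonlite::write_json(
    list(P = eq$P, A = eq$A, converged = eq$converged,
         stable = eq$stable, persistence = eq$persistence,
         steps_used = eq$steps_used),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
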