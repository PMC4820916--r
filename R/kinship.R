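#' Pedigree tables
#'
#' A pedigree is a tibble with columns `id`, `father`, `mother`, `sex`
#' (1 = male, 2 = female; founders have `NA` parents). `as_pedigree()`
#' validates a data frame: ids unique, parents present, parent sexes
#' consistent, no individual its own ancestor.
#'
#' @param data Data frame with columns `id`, `father`, `mother`, `sex`.
#'   `father`/`mother` may use `NA`, `"0"` or `0` for founders.
#' @return A validated `pedigree` tibble (ids as character).
#' @export
as_pedigree <- function(data) {
  assert_columns(data, c("id", "father", "mother", "sex"), "pedigree")
  ped <- tibble::tibble(
    id = as.character(data$id),
    father = as.character(data$father),
    mother = as.character(data$mother),
    sex = as.integer(data$sex)
  )
  ped$father[ped$father %in% c("0", "NA", "")] <- NA_character_
  ped$mother[ped$mother %in% c("0", "NA", "")] <- NA_character_
  if (anyDuplicated(ped$id)) stop("duplicate pedigree ids", call. = FALSE)
  for (col in c("father", "mother")) {
    known <- ped[[col]][!is.na(ped[[col]])]
    bad <- setdiff(known, ped$id)
    if (length(bad) > 0L) {
      stop(sprintf("unknown %s id(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  idx <- match(ped$id, ped$id)
  f_sex <- ped$sex[match(ped$father, ped$id)]
  m_sex <- ped$sex[match(ped$mother, ped$id)]
  if (any(f_sex != 1L, na.rm = TRUE) || any(m_sex != 2L, na.rm = TRUE)) {
    stop("parent sexes inconsistent (father must be male, mother female)",
         call. = FALSE)
  }
  ped_order(ped) # errors on cycles
  class(ped) <- c("pedigree", class(ped))
  ped
}

# Topological order (founders first). Errors if a cycle exists.
ped_order <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fi) | placed[ifelse(is.na(fi), 1L, fi)]) &
      (is.na(mi) | placed[ifelse(is.na(mi), 1L, mi)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle (individual is its own ancestor)",
         call. = FALSE)
  }
  ord
}

#' Relationship matrix from a pedigree
#'
#' Computes pairwise kinship coefficients by the classical founder-down
#' recursion (founders unrelated and non-inbred; for individual `i` with
#' parents `f`, `m`: `phi(i, j) = (phi(f, j) + phi(m, j)) / 2` for prior
#' `j`, and `phi(i, i) = (1 + phi(f, m)) / 2`), then doubles them to the
#' reporting scale on which self and identical twins score 1,
#' parent-offspring and full siblings 0.5, and grandparent-grandchild,
#' avuncular, half-siblings and double first cousins 0.25.
#'
#' Some literature tabulates much smaller coefficients for 3rd-6th degree
#' relatives (0.0078 ... 0.0001); those values are not consistent with the
#' classical recursion (first cousins are 0.125 on this scale) and are not
#' reproduced here.
#'
#' @param pedigree A [as_pedigree()] table (coerced if plain data frame).
#' @param scale `"reporting"` (default, 2*phi, self = 1) or `"kinship"`
#'   (phi, self = 0.5).
#' @return Symmetric positive semi-definite matrix with row/column names
#'   equal to pedigree ids.
#' @examples
#' ped <- tibble::tibble(id = c("f", "m", "c"),
#'                       father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
#'                       sex = c(1, 2, 1))
#' build_relationship_matrix(ped)["f", "c"] # 0.5
#' @export
build_relationship_matrix <- function(pedigree,
                                      scale = c("reporting", "kinship")) {
  scale <- match.arg(scale)
  ped <- if (inherits(pedigree, "pedigree")) pedigree else as_pedigree(pedigree)
  if (nrow(ped) == 0L) stop("empty pedigree", call. = FALSE)
  ord <- ped_order(ped)
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    f <- fi[i]; m <- mi[i]
    if (is.na(f) && is.na(m)) {
      phi[i, i] <- 0.5
    } else {
      prev <- setdiff(seq_len(n), i)
      pf <- if (is.na(f)) 0 else phi[f, prev]
      pm <- if (is.na(m)) 0 else phi[m, prev]
      phi[i, prev] <- (pf + pm) / 2
      phi[prev, i] <- phi[i, prev]
      phi[i, i] <- 0.5 * (1 + if (is.na(f) || is.na(m)) 0 else phi[f, m])
    }
  }
  if (scale == "reporting") 2 * phi else phi
}

#' Relationship coefficient of a pair
#'
#' @param pedigree A pedigree table.
#' @param a,b Subject ids.
#' @inheritParams build_relationship_matrix
#' @return The (a, b) entry of [build_relationship_matrix()]; symmetric in
#'   its arguments.
#' @export
relationship_of <- function(pedigree, a, b,
                            scale = c("reporting", "kinship")) {
  scale <- match.arg(scale)
  ped <- if (inherits(pedigree, "pedigree")) pedigree else as_pedigree(pedigree)
  a <- as.character(a); b <- as.character(b)
  bad <- setdiff(c(a, b), ped$id)
  if (length(bad) > 0L) {
    stop(sprintf("unknown id(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  build_relationship_matrix(ped, scale = scale)[a, b]
}

#' Read / write PED-style pedigree files
#'
#' Whitespace-delimited files with columns id, father, mother, sex
#' (0 = missing parent), optionally preceded by a family-id column when
#' `family = TRUE`.
#'
#' @param path File path.
#' @param family Does the file carry a leading family-id column?
#' @return `read_ped()`: a pedigree tibble (with a `family` column when
#'   present); `write_ped()`: the path, invisibly.
#' @export
read_ped <- function(path, family = FALSE) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- if (family) c("family", "id", "father", "mother", "sex") else
    c("id", "father", "mother", "sex")
  if (ncol(raw) < length(cols)) stop("too few columns in PED file", call. = FALSE)
  names(raw)[seq_along(cols)] <- cols
  ped <- as_pedigree(raw[, setdiff(cols, "family"), drop = FALSE])
  if (family) ped$family <- as.character(raw$family)
  ped
}

#' @rdname read_ped
#' @param pedigree Pedigree table to write.
#' @export
write_ped <- function(pedigree, path) {
  ped <- if (inherits(pedigree, "pedigree")) pedigree else as_pedigree(pedigree)
  out <- data.frame(
    id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ped$sex
  )
  if ("family" %in% names(pedigree)) out <- cbind(family = pedigree$family, out)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a relationship matrix as TSV
#'
#' Dense TSV with a header row and leading id column, or sparse triplet
#' form (`id_a`, `id_b`, `coefficient`, non-zero upper triangle).
#'
#' @param mat Matrix from [build_relationship_matrix()].
#' @param path Output path.
#' @param format `"dense"` or `"triplet"`.
#' @export
write_relationship_tsv <- function(mat, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
    df <- data.frame(id_a = rownames(mat)[idx[, 1]],
                     id_b = colnames(mat)[idx[, 2]],
                     coefficient = mat[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
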