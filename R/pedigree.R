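#' Construct a pedigree
#'
#' A pedigree is a table of individuals grouped into families, with optional
#' parentage links. Founders have both parent fields missing; non-founders must
#' have both parents present in the same family. Individuals flagged as
#' unsampled (e.g. deceased founders) take part in kinship computations but are
#' excluded from data matrices.
#'
#' @param fam character vector of family identifiers.
#' @param id character vector of individual identifiers, unique across the
#'   whole pedigree.
#' @param father,mother character vectors of parent identifiers, `NA` for
#'   founders.
#' @param sex integer vector (1 = male, 2 = female, `NA` = unknown).
#' @param sampled logical vector; `FALSE` marks individuals without phenotype
#'   data (kinship-only).
#' @return An object of class `pedigree`: a data frame with the columns above.
#' @export
pedigree <- function(fam, id, father = NA, mother = NA, sex = NA,
                     sampled = TRUE) {
  ped <- data.frame(
    fam = as.character(fam), id = as.character(id),
    father = as.character(father), mother = as.character(mother),
    sex = as.integer(sex), sampled = as.logical(sampled),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  abort_if(anyDuplicated(ped$id) > 0, "duplicated individual ids in pedigree")
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  for (side in c("father", "mother")) {
    p <- ped[[side]]
    miss <- !is.na(p) & !(p %in% ped$id)
    abort_if(any(miss), sprintf(
      "individual '%s': %s '%s' not found in pedigree",
      ped$id[which(miss)[1L]], side, p[which(miss)[1L]]
    ))
    cross <- !is.na(p) & ped$fam[idx[p]] != ped$fam
    abort_if(any(cross), sprintf(
      "individual '%s': %s belongs to a different family",
      ped$id[which(cross)[1L]], side
    ))
  }
  one_parent <- xor(is.na(ped$father), is.na(ped$mother))
  abort_if(any(one_parent), sprintf(
    "individual '%s' has exactly one known parent; founders must have none",
    ped$id[which(one_parent)[1L]]
  ))
  invisible(pedigree_depths(ped)) # errors on parentage cycles
}

# Generation depth of each individual: founders 0, children 1 + max(parents).
# Errors if the parentage graph has a cycle.
pedigree_depths <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  depth <- ifelse(is.na(ped$father), 0L, NA_integer_)
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    fa <- depth[idx[ped$father[todo]]]
    mo <- depth[idx[ped$mother[todo]]]
    ready <- !is.na(fa) & !is.na(mo)
    abort_if(!any(ready), sprintf(
      "parentage cycle detected involving individual '%s'", ped$id[todo[1L]]
    ))
    depth[todo[ready]] <- 1L + pmax(fa[ready], mo[ready])
  }
  depth
}

#' Read and write PED-style pedigree files
#'
#' Whitespace-delimited files with columns family id, individual id, father id,
#' mother id, and sex; missing parents are coded `"0"`. An optional sixth
#' column holds the sampled flag (1/0); when absent every individual is taken
#' as sampled.
#'
#' @param path file path.
#' @return `read_ped()` returns a [pedigree]; `write_ped()` returns `path`
#'   invisibly.
#' @export
read_ped <- function(path) {
  abort_if(!file.exists(path), sprintf("pedigree file '%s' not found", path))
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse PED file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  abort_if(ncol(tab) < 5L,
           sprintf("PED file '%s' needs >= 5 columns, found %d", path, ncol(tab)))
  clean <- function(x) ifelse(x %in% c("0", "", "NA"), NA_character_, x)
  pedigree(
    fam = tab[[1L]], id = tab[[2L]],
    father = clean(tab[[3L]]), mother = clean(tab[[4L]]),
    sex = suppressWarnings(as.integer(tab[[5L]])),
    sampled = if (ncol(tab) >= 6L) tab[[6L]] != "0" else TRUE
  )
}

#' @param ped a [pedigree].
#' @rdname read_ped
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(
    fam = ped$fam, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(is.na(ped$sex), "0", as.character(ped$sex)),
    sampled = ifelse(ped$sampled, "1", "0")
  )
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Additive genetic relationship matrix from a pedigree
#'
#' Computes the additive relationship matrix A = 2K (twice the kinship
#' coefficients) by the standard recursive tabular method: processing
#' individuals so that parents precede children,
#' `A[i,i] = 1 + A[father(i), mother(i)] / 2` and
#' `A[i,j] = (A[j, father(i)] + A[j, mother(i)]) / 2`, with founders taken as
#' unrelated and non-inbred. The result is restricted to sampled individuals
#' and stored per family block, since individuals in different families are
#' unrelated.
#'
#' @param ped a [pedigree].
#' @return An object of class `kinship_matrix` with fields `ids` (sampled
#'   individual ids, in pedigree order), `fam` (factor of family of each id),
#'   and `blocks` (named list of per-family dense matrices `A_f`).
#' @export
kinship_from_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  depth <- pedigree_depths(ped)
  fams <- unique(ped$fam)
  blocks <- vector("list", length(fams))
  names(blocks) <- fams
  for (f in fams) {
    rows <- which(ped$fam == f)
    ord <- rows[order(depth[rows])]
    m <- length(ord)
    ids <- ped$id[ord]
    pos <- stats::setNames(seq_len(m), ids)
    A <- matrix(0, m, m, dimnames = list(ids, ids))
    for (k in seq_len(m)) {
      i <- ord[k]
      if (is.na(ped$father[i])) {
        A[k, k] <- 1
      } else {
        fa <- pos[ped$father[i]]
        mo <- pos[ped$mother[i]]
        if (k > 1L) {
          prev <- seq_len(k - 1L)
          A[k, prev] <- (A[prev, fa] + A[prev, mo]) / 2
          A[prev, k] <- A[k, prev]
        }
        A[k, k] <- 1 + A[fa, mo] / 2
      }
    }
    # restrict to sampled individuals, in original pedigree row order so that
    # kinship ids align with data rows
    keep <- ped$id[rows][ped$sampled[rows]]
    blocks[[f]] <- A[keep, keep, drop = FALSE]
  }
  blocks <- blocks[vapply(blocks, nrow, 0L) > 0L]
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  structure(
    list(ids = ids,
         fam = factor(rep(names(blocks), vapply(blocks, nrow, 0L)),
                      levels = names(blocks)),
         blocks = blocks),
    class = "kinship_matrix"
  )
}

#' @export
as.matrix.kinship_matrix <- function(x, ...) {
  A <- as.matrix(Matrix::bdiag(x$blocks))
  dimnames(A) <- list(x$ids, x$ids)
  A
}

#' @export
dim.kinship_matrix <- function(x) rep(length(x$ids), 2L)

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d sampled individuals in %d families\n",
              length(x$ids), length(x$blocks)))
  invisible(x)
}

#' Export a kinship matrix as TSV
#'
#' Writes the dense additive relationship matrix with individual ids as header
#' row and leading column.
#'
#' @param kin a `kinship_matrix`.
#' @param path output file path.
#' @export
write_kinship_tsv <- function(kin, path) {
  A <- as.matrix(kin)
  out <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

# -- synthetic cohorts -------------------------------------------------------

cohort_templates <- list(
  # Two full siblings whose parents are unsampled, each with an unrelated
  # spouse and two children: 8 sampled members per family, with pairwise
  # relationships spanning 2k in {0.5 (sib, parent-child), 0.25 (avuncular),
  # 0.125 (first cousins), 0 (spouses)}.
  llfs8 = data.frame(
    id = c("GF", "GM", "S1", "S2", "P1", "P2", "C11", "C12", "C21", "C22"),
    father = c(NA, NA, "GF", "GF", NA, NA, "S1", "S1", "S2", "S2"),
    mother = c(NA, NA, "GM", "GM", NA, NA, "P1", "P1", "P2", "P2"),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L),
    sampled = c(FALSE, FALSE, rep(TRUE, 8L)),
    stringsAsFactors = FALSE
  ),
  sibpair = data.frame(
    id = c("GF", "GM", "S1", "S2"),
    father = c(NA, NA, "GF", "GF"),
    mother = c(NA, NA, "GM", "GM"),
    sex = c(1L, 2L, 1L, 2L),
    sampled = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ),
  trio = data.frame(
    id = c("FA", "MO", "CH"),
    father = c(NA, NA, "FA"),
    mother = c(NA, NA, "MO"),
    sex = c(1L, 2L, 1L),
    sampled = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ),
  singleton = data.frame(
    id = "I1", father = NA_character_, mother = NA_character_,
    sex = 1L, sampled = TRUE, stringsAsFactors = FALSE
  )
)

#' Generate a synthetic family cohort
#'
#' Replicates a family template `n_families` times. The default template
#' (`"llfs8"`) mirrors the composition of a family study of aging in which a
#' typical enrolled family has a proband and a consenting sibling, their
#' spouses, and their offspring: 8 sampled members per family whose pairwise
#' additive relationships cover sibling/parent-child (0.5), avuncular (0.25),
#' first-cousin (0.125), and unrelated-spouse (0) values. 582 such families
#' give a cohort of 4656 sampled individuals.
#'
#' @param n_families number of family copies (>= 1).
#' @param family_template one of `"llfs8"`, `"sibpair"`, `"trio"`,
#'   `"singleton"`.
#' @param seed optional integer seed (templates are deterministic; the seed is
#'   accepted for interface stability with stochastic templates).
#' @return A [pedigree].
#' @export
make_synthetic_cohort <- function(n_families, family_template = "llfs8",
                                  seed = NULL) {
  abort_if(!is.numeric(n_families) || n_families < 1,
           "n_families must be a count >= 1")
  abort_if(!family_template %in% names(cohort_templates), sprintf(
    "unknown family template '%s' (available: %s)", family_template,
    paste(names(cohort_templates), collapse = ", ")
  ))
  tpl <- cohort_templates[[family_template]]
  n_families <- as.integer(n_families)
  m <- nrow(tpl)
  fam <- rep(sprintf("F%04d", seq_len(n_families)), each = m)
  tag <- function(x) ifelse(is.na(x), NA_character_, paste0(fam, "_", x))
  ped <- data.frame(
    fam = fam,
    id = paste0(fam, "_", rep(tpl$id, n_families)),
    father = tag(rep(tpl$father, n_families)),
    mother = tag(rep(tpl$mother, n_families)),
    sex = rep(tpl$sex, n_families),
    sampled = rep(tpl$sampled, n_families),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Transmission "waves": groups of individuals whose parents all appear in
# earlier waves, so allele transmission can be vectorized per wave.
pedigree_waves <- function(ped) {
  depth <- pedigree_depths(ped)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  lapply(sort(unique(depth[depth > 0L])), function(d) {
    who <- which(depth == d)
    list(child = who, father = idx[ped$father[who]],
         mother = idx[ped$mother[who]])
  })
}

#' Gene-drop SNP genotypes down a pedigree
#'
#' For each SNP, founder alleles are drawn as Bernoulli(p) with allele
#' frequency p drawn uniformly on `(maf_min, 0.5)`; non-founder alleles are
#' transmitted by Mendelian sampling (one random allele from each parent).
#' Columns whose realized sample minor allele frequency among sampled
#' individuals falls below `maf_min` are redrawn with a fresh allele
#' frequency.
#'
#' @param ped a [pedigree].
#' @param q number of SNP columns (>= 1).
#' @param maf_min minimum sample minor allele frequency, in (0, 0.5).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A matrix of allele counts in {0, 1, 2} with one row per sampled
#'   individual (rownames = ids) and attribute `"maf"` holding realized sample
#'   minor allele frequencies.
#' @export
gene_drop_snps <- function(ped, q, maf_min = 0.05, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  abort_if(!is.numeric(q) || q < 1, "q must be a count >= 1")
  abort_if(maf_min <= 0 || maf_min >= 0.5, "maf_min must be in (0, 0.5)")
  q <- as.integer(q)
  with_seed(seed, {
    waves <- pedigree_waves(ped)
    founders <- which(is.na(ped$father))
    sampled <- which(ped$sampled)
    n_all <- nrow(ped)
    drop_cols <- function(k) {
      p <- stats::runif(k, maf_min, 0.5)
      a1 <- matrix(0L, n_all, k)
      a2 <- matrix(0L, n_all, k)
      pf <- matrix(p, length(founders), k, byrow = TRUE)
      a1[founders, ] <- (stats::runif(length(founders) * k) < pf) + 0L
      a2[founders, ] <- (stats::runif(length(founders) * k) < pf) + 0L
      for (w in waves) {
        nw <- length(w$child)
        pick <- stats::runif(nw * k) < 0.5
        a1[w$child, ] <- ifelse(pick, a1[w$father, ], a2[w$father, ])
        pick <- stats::runif(nw * k) < 0.5
        a2[w$child, ] <- ifelse(pick, a1[w$mother, ], a2[w$mother, ])
      }
      (a1 + a2)[sampled, , drop = FALSE]
    }
    G <- drop_cols(q)
    maf_of <- function(g) pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
    for (it in seq_len(200L)) {
      bad <- which(maf_of(G) < maf_min)
      if (length(bad) == 0L) break
      G[, bad] <- drop_cols(length(bad))
    }
    abort_if(length(which(maf_of(G) < maf_min)) > 0L,
             "could not reach requested minor allele frequency; raise maf_min?")
    dimnames(G) <- list(ped$id[sampled], sprintf("snp%02d", seq_len(q)))
    attr(G, "maf") <- maf_of(G)
    G
  })
}
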