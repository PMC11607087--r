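#' Construct a pedigree object
#'
#' @param id Character vector of individual identifiers (unique).
#' @param dam,sire Character vectors of parent identifiers; `NA` or `""`
#'   means unknown. Parents named but lacking their own record are auto-added
#'   as founders.
#' @return A data.frame of class `pedigree` with columns `id`, `dam`, `sire`,
#'   topologically sorted so parents precede offspring.
#' @export
pedigree <- function(id, dam = NA, sire = NA) {
  id <- as.character(id)
  norm <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    rep_len(x, length(id))
  }
  dam <- norm(dam); sire <- norm(sire)
  if (anyDuplicated(id))
    stop("duplicate id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  parents <- setdiff(stats::na.omit(c(dam, sire)), id)
  if (length(parents)) {
    id <- c(parents, id)
    dam <- c(rep(NA_character_, length(parents)), dam)
    sire <- c(rep(NA_character_, length(parents)), sire)
  }
  ped <- data.frame(id = id, dam = dam, sire = sire,
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  sort_pedigree(ped)
}

#' Topologically sort a pedigree (parents before offspring)
#'
#' Kahn's algorithm over the parent->offspring DAG; a cycle (an individual
#' that is its own ancestor) is reported with the ids involved.
#'
#' @param ped A `pedigree` (or data.frame with id/dam/sire columns).
#' @return The sorted `pedigree`.
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- function(x) match(x, ped$id)
  pd <- idx(ped$dam); ps <- idx(ped$sire)
  if (any(!is.na(ped$dam) & is.na(pd)) || any(!is.na(ped$sire) & is.na(ps)))
    stop("named parent without a record; build with pedigree() to auto-add")
  indeg <- integer(n)
  kids <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(pd[j], ps[j])) {
      if (!is.na(p)) {
        indeg[j] <- indeg[j] + 1L
        kids[[p]] <- c(kids[[p]], j)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    j <- queue[1L]; queue <- queue[-1L]
    order <- c(order, j)
    for (k in kids[[j]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n)
    stop("pedigree cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), order)], collapse = ", "))
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Additive genetic relationship matrix (tabular method)
#'
#' For a sorted pedigree, a_jj = 1 + 0.5 a(dam_j, sire_j) and
#' a_ij = 0.5 (a(i, dam_j) + a(i, sire_j)) for i earlier than j; an unknown
#' parent contributes 0 (founders assumed unrelated and non-inbred).
#'
#' @param ped A `pedigree`.
#' @return Symmetric numeric matrix with the pedigree ids as dimnames;
#'   diagonal is 1 + F (F the inbreeding coefficient).
#' @export
additive_relationship <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  pd <- match(ped$dam, ped$id); ps <- match(ped$sire, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    d <- pd[j]; s <- ps[j]
    aj <- numeric(n)
    if (j > 1L) {
      i <- seq_len(j - 1L)
      if (!is.na(d)) aj[i] <- aj[i] + 0.5 * A[i, d]
      if (!is.na(s)) aj[i] <- aj[i] + 0.5 * A[i, s]
      A[i, j] <- aj[i]
      A[j, i] <- aj[i]
    }
    A[j, j] <- 1 + if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
  }
  A
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' @param ped A `pedigree`.
#' @param keep Ids of phenotyped individuals.
#' @return The `pedigree` restricted to `keep` plus all their ancestors.
#' @export
prune_pedigree <- function(ped, keep) {
  miss <- setdiff(keep, ped$id)
  if (length(miss))
    stop("ids not in pedigree: ", paste(miss, collapse = ", "))
  need <- unique(as.character(keep))
  repeat {
    rows <- ped[ped$id %in% need, , drop = FALSE]
    more <- setdiff(stats::na.omit(c(rows$dam, rows$sire)), need)
    if (!length(more)) break
    need <- c(need, more)
  }
  out <- ped[ped$id %in% need, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  sort_pedigree(out)
}

#' Permute parentage keeping the dam-sire pair architecture
#'
#' The multiset of dam-sire pairs among the focal offspring is preserved:
#' sibships (offspring sharing an identical dam-sire pair) keep their
#' sizes, and parent pairs are randomly reassigned across sibships of the
#' same size (so each offspring-level pair count is unchanged and litters
#' stay intact). Used to build the null distribution for additive genetic
#' variance.
#'
#' @param ped A `pedigree`.
#' @param offspring_ids Offspring whose parentage is shuffled.
#' @param seed Integer seed (reproducible permutation).
#' @param max_tries Resampling attempts if a draw would make an individual
#'   its own ancestor.
#' @return A new valid `pedigree` with permuted parent pairs.
#' @export
permute_parentage <- function(ped, offspring_ids, seed, max_tries = 100L) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(all(offspring_ids %in% ped$id))
  rows <- match(offspring_ids, ped$id)
  key <- paste(ped$dam[rows], ped$sire[rows], sep = "\r")
  sibships <- split(rows, key)           # sibship = identical dam-sire pair
  pair_dam <- vapply(sibships, function(r) ped$dam[r[1L]], "")
  pair_sire <- vapply(sibships, function(r) ped$sire[r[1L]], "")
  m <- length(sibships)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  sizes <- lengths(sibships)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    perm <- seq_len(m)
    for (sz in unique(sizes)) {        # permute within size classes
      cls <- which(sizes == sz)
      if (length(cls) > 1L) perm[cls] <- cls[sample.int(length(cls))]
    }
    cand <- ped
    for (k in seq_len(m)) {
      r <- sibships[[k]]
      cand$dam[r] <- pair_dam[perm[k]]
      cand$sire[r] <- pair_sire[perm[k]]
    }
    sorted <- tryCatch(sort_pedigree(cand), error = function(e) NULL)
    if (!is.null(sorted)) return(sorted)
  }
  stop("could not find an acyclic permutation in ", max_tries, " tries")
}

#' Read / write pedigree CSV (columns id, dam, sire; empty cell = unknown)
#'
#' @param path CSV path.
#' @return [read_pedigree()]: a sorted `pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(df)))
    stop("pedigree CSV needs columns id, dam, sire")
  pedigree(df$id, df$dam, df$sire)
}

#' @rdname read_pedigree
#' @param ped A `pedigree` to write.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$dam[is.na(out$dam)] <- ""
  out$sire[is.na(out$sire)] <- ""
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
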