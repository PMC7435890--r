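# Nine-fingerprint Tanimoto baseline.  Bit vectors come from the standard
# cheminformatics toolkit; the Tanimoto computation, ranking and table
# assembly are done here.  Hashed fingerprints default to radius 2 and
# 1024 bits, the parameterization under which the published
# clozapine-vs-inhibitor Tanimoto panel reproduces to the printed precision.
# MACCS (167 keys), RDKit, Layered, Pattern and Avalon use their standard
# fixed lengths.

#' The nine supported fingerprint methods
#' @return Character vector of method names.
#' @export
fingerprint_methods <- function() {
  c("atompair", "avalon", "featmorgan", "layered", "maccs",
    "morgan", "pattern", "rdkit", "torsion")
}

#' Compute a molecular fingerprint
#'
#' @param smiles A single valid SMILES string.
#' @param method One of [fingerprint_methods()].
#' @param radius Neighbourhood radius for the circular (Morgan/FeatMorgan)
#'   fingerprints.
#' @param nbits Bit-vector length for the hashed fingerprints (atom pair,
#'   torsion, Morgan, FeatMorgan); fixed-length methods ignore it.
#' @return A `fingerprint` object: set-bit positions (0-based), vector
#'   length, method and parameters.
#' @examples
#' \dontrun{
#' fp <- compute_fingerprint(load_bundled_set("table1_inhibitors")$smiles[1],
#'                           "maccs")
#' fp$nbits  # 167
#' }
#' @export
compute_fingerprint <- function(smiles, method, radius = 2L, nbits = 1024L) {
  stopifnot(length(smiles) == 1L)
  compute_fingerprints(smiles, method, radius = radius, nbits = nbits)[[1]]
}

#' Compute fingerprints for a batch of molecules
#'
#' Same as [compute_fingerprint()] but one toolkit call for a whole vector.
#'
#' @inheritParams compute_fingerprint
#' @param smiles Character vector of valid SMILES.
#' @return List of `fingerprint` objects.
#' @export
compute_fingerprints <- function(smiles, method, radius = 2L, nbits = 1024L) {
  method <- match.arg(method, fingerprint_methods())
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  out <- run_chem_tool(
    c("fp", "--method", method, "--radius", as.integer(radius),
      "--nbits", as.integer(nbits)),
    input = smiles
  )
  if (length(out) != length(smiles)) {
    abort("fingerprint helper returned the wrong number of records")
  }
  bad <- which(out == "!")
  if (length(bad) > 0L) {
    abort(sprintf("invalid SMILES at position(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  lapply(out, function(line) {
    parts <- strsplit(line, ":", fixed = TRUE)[[1]]
    bits <- if (length(parts) > 1L && nzchar(parts[2])) {
      as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    } else {
      integer(0)
    }
    structure(
      list(bits = bits, nbits = as.integer(parts[1]), method = method,
           params = list(radius = as.integer(radius),
                         nbits = as.integer(nbits))),
      class = "fingerprint"
    )
  })
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s, %d/%d bits set\n", x$method,
              length(x$bits), x$nbits))
  invisible(x)
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over set bits; defined as 1 when both vectors are
#' all-zero.  Both fingerprints must come from the same method.
#'
#' @param a,b `fingerprint` objects of matching method and length.
#' @return Scalar in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$method != b$method || a$nbits != b$nbits) {
    abort(sprintf("fingerprint mismatch: %s/%d vs %s/%d",
                  a$method, a$nbits, b$method, b$nbits))
  }
  union_n <- length(union(a$bits, b$bits))
  if (union_n == 0L) return(1)
  length(intersect(a$bits, b$bits)) / union_n
}

# Tanimoto of one query fingerprint against a list of fingerprints.
tanimoto_vec <- function(query, fps) {
  vapply(fps, function(f) tanimoto(query, f), numeric(1))
}

#' Top-k similarity table across all fingerprint methods
#'
#' For each method, candidates are ranked by Tanimoto similarity to the
#' query; a cell holds the similarity when that candidate is within the top
#' `k` for that method, and `NA` otherwise (the table's "absent" marker).
#' This reproduces the layout of published query-vs-panel comparisons, where
#' presence in the "top 50" differs sharply between encodings.
#'
#' @param query A single valid SMILES string.
#' @param candidates Tibble with `id` and `smiles` columns, or a named
#'   character vector of SMILES.
#' @param methods Fingerprint methods to include (default all nine).
#' @param k Rank cutoff (default 50).
#' @param radius,nbits Parameters for the hashed fingerprints.
#' @return Tibble with column `id` plus one numeric column per method;
#'   attributes `rdkit_version`, `params` and `k` record provenance.
#' @export
top50_table <- function(query, candidates, methods = fingerprint_methods(),
                        k = 50L, radius = 2L, nbits = 1024L) {
  if (is.character(candidates)) {
    ids <- names(candidates) %||% sprintf("mol_%05d", seq_along(candidates))
    candidates <- tibble(id = ids, smiles = unname(candidates))
  }
  stopifnot(all(c("id", "smiles") %in% names(candidates)),
            nrow(candidates) >= 1L)
  methods <- match.arg(methods, fingerprint_methods(), several.ok = TRUE)
  cols <- lapply(methods, function(m) {
    fps <- compute_fingerprints(c(query, candidates$smiles), m,
                                radius = radius, nbits = nbits)
    ts <- tanimoto_vec(fps[[1]], fps[-1])
    keep_rank <- rank(-ts, ties.method = "min") <= k
    ifelse(keep_rank, ts, NA_real_)
  })
  names(cols) <- methods
  out <- dplyr::bind_cols(tibble(id = candidates$id), tibble(!!!cols))
  attr(out, "rdkit_version") <- rdkit_version()
  attr(out, "params") <- list(radius = radius, nbits = nbits)
  attr(out, "k") <- as.integer(k)
  out
}

#' Best-metabolite similarity under a fingerprint versus the latent metric
#'
#' For each drug, finds its best Tanimoto similarity to any metabolite under
#' the chosen fingerprint, and its best latent-space (E-Sim) similarity to
#' any metabolite from the supplied embeddings — the paired table behind
#' fingerprint-vs-latent scatter comparisons.  The Spearman rank correlation
#' between the two columns is attached as attribute `spearman`.
#'
#' @param drugs,metabolites Tibbles with `id` and `smiles` columns.
#' @param fp_method One of [fingerprint_methods()].
#' @param vae_embeddings Embedding tibble covering every drug and metabolite
#'   id.
#' @param radius,nbits Fingerprint parameters.
#' @param squared Use the squared-distance similarity variant for E-Sim.
#' @return Tibble `drug_id`, `ts_best`, `ts_best_metabolite`, `esim_best`,
#'   `esim_best_metabolite`, in drug input order.
#' @export
fingerprint_vs_vae_scatter <- function(drugs, metabolites, fp_method,
                                       vae_embeddings, radius = 2L,
                                       nbits = 1024L, squared = FALSE) {
  stopifnot(all(c("id", "smiles") %in% names(drugs)),
            all(c("id", "smiles") %in% names(metabolites)))
  missing_ids <- setdiff(c(drugs$id, metabolites$id), vae_embeddings$id)
  if (length(missing_ids) > 0L) {
    abort(sprintf("ids missing from vae_embeddings: %s",
                  paste(head(missing_ids, 5L), collapse = ", ")))
  }
  fp_method <- match.arg(fp_method, fingerprint_methods())

  fps <- compute_fingerprints(c(drugs$smiles, metabolites$smiles), fp_method,
                              radius = radius, nbits = nbits)
  fp_d <- fps[seq_len(nrow(drugs))]
  fp_m <- fps[-seq_len(nrow(drugs))]
  ts <- vapply(fp_d, function(f) {
    v <- tanimoto_vec(f, fp_m)
    j <- which.max(v)
    c(v[j], j)
  }, numeric(2))

  emb_d <- vae_embeddings[match(drugs$id, vae_embeddings$id), , drop = FALSE]
  emb_m <- vae_embeddings[match(metabolites$id, vae_embeddings$id), , drop = FALSE]
  ranked <- rank_order_best_match(emb_d, emb_m, metric = "e", squared = squared)
  es <- ranked[match(drugs$id, ranked$drug_id), , drop = FALSE]

  out <- tibble(
    drug_id = drugs$id,
    ts_best = ts[1L, ],
    ts_best_metabolite = metabolites$id[ts[2L, ]],
    esim_best = es$similarity,
    esim_best_metabolite = es$best_metabolite_id
  )
  attr(out, "spearman") <- stats::cor(out$ts_best, out$esim_best,
                                      method = "spearman")
  attr(out, "fp_method") <- fp_method
  out
}
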