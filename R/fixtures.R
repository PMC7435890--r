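#' Specification for the synthetic small-molecule generator
#'
#' The generator stands in for the multi-million-molecule drug-like corpus
#' used at full scale: it assembles random acyclic skeletons (optionally with
#' one ring closure) over a small atom alphabet, with valence bookkeeping so
#' that every emitted string is legal SMILES, then validates and
#' canonicalizes each molecule with the chemistry toolkit.  Molecules are
#' deliberately small so that a reduced autoencoder trains in minutes.
#'
#' @param n_molecules Number of unique molecules to produce.
#' @param max_heavy_atoms Upper bound on heavy-atom count per molecule.
#' @param atom_alphabet Subset of `c("C","N","O","S","F")`.
#' @param ring_probability Probability that a molecule carries one ring.
#' @param branch_probability Probability that a new atom starts a branch
#'   rather than extending the current chain.
#' @param seed Integer seed; the whole generation run is a pure function of
#'   the spec including this seed.
#' @param max_smiles_len Reject molecules whose canonical SMILES exceeds this
#'   length, so all output fits the reduced model's padded window.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules,
                           max_heavy_atoms = 14L,
                           atom_alphabet = c("C", "N", "O", "S", "F"),
                           ring_probability = 0.3,
                           branch_probability = 0.25,
                           seed = 1L,
                           max_smiles_len = 24L) {
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 1L,
            ring_probability >= 0, ring_probability <= 1,
            branch_probability >= 0, branch_probability <= 1)
  if (!all(atom_alphabet %in% c("C", "N", "O", "S", "F")) ||
      length(atom_alphabet) == 0L) {
    abort("atom_alphabet must be a non-empty subset of C, N, O, S, F")
  }
  structure(
    list(n_molecules = as.integer(n_molecules),
         max_heavy_atoms = as.integer(max_heavy_atoms),
         atom_alphabet = atom_alphabet,
         ring_probability = ring_probability,
         branch_probability = branch_probability,
         seed = as.integer(seed),
         max_smiles_len = as.integer(max_smiles_len)),
    class = "synthetic_spec"
  )
}

ATOM_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L)
# sampling weights: carbon-rich molecules, heteroatoms as decoration
ATOM_WEIGHT <- c(C = 0.70, N = 0.10, O = 0.12, S = 0.04, F = 0.04)

# One random molecule as a SMILES string (single bonds, at most one ring).
random_molecule_smiles <- function(spec) {
  alphabet <- spec$atom_alphabet
  w <- ATOM_WEIGHT[alphabet] / sum(ATOM_WEIGHT[alphabet])
  lo <- min(3L, spec$max_heavy_atoms)
  n <- sample_one(seq(lo, spec$max_heavy_atoms))

  elem <- character(n)
  deg <- integer(n)
  children <- vector("list", n)
  parent <- integer(n)

  non_terminal <- alphabet[ATOM_VALENCE[alphabet] >= 2L]
  if (length(non_terminal) == 0L) non_terminal <- alphabet
  elem[1] <- if (n == 1L) {
    sample(alphabet, 1L, prob = w)
  } else {
    sample_one(non_terminal)
  }
  last_added <- 1L
  if (n > 1L) {
    for (j in 2:n) {
      placed <- seq_len(j - 1L)
      open <- placed[deg[placed] < ATOM_VALENCE[elem[placed]]]
      if (length(open) == 0L) { n <- j - 1L; break }
      p <- if (last_added %in% open && runif(1) > spec$branch_probability) {
        last_added
      } else {
        sample_one(open)
      }
      # keep terminal atoms off the backbone while the molecule is still growing
      pool <- if (j < n) non_terminal else alphabet
      elem[j] <- sample(pool, 1L, prob = ATOM_WEIGHT[pool] / sum(ATOM_WEIGHT[pool]))
      parent[j] <- p
      children[[p]] <- c(children[[p]], j)
      deg[p] <- deg[p] + 1L
      deg[j] <- deg[j] + 1L
      last_added <- j
    }
  }
  elem <- elem[seq_len(n)]

  # optional single ring: an extra bond between atoms at tree distance 4-5
  ring <- integer(0)
  if (n >= 5L && runif(1) < spec$ring_probability) {
    depth <- integer(n)
    for (j in seq_len(n)[-1]) depth[j] <- depth[parent[j]] + 1L
    spare <- which(deg < ATOM_VALENCE[elem])
    cand <- NULL
    if (length(spare) >= 2L) {
      pairs <- expand.grid(a = spare, b = spare)
      pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
      if (nrow(pairs) > 0L) {
        dist <- mapply(tree_distance, pairs$a, pairs$b,
                       MoreArgs = list(parent = parent, depth = depth))
        cand <- pairs[dist >= 4L & dist <= 5L, , drop = FALSE]
      }
    }
    if (!is.null(cand) && nrow(cand) > 0L) {
      k <- sample.int(nrow(cand), 1L)
      ring <- c(cand$a[k], cand$b[k])
      deg[ring] <- deg[ring] + 1L
    }
  }

  emit <- function(i) {
    s <- elem[i]
    if (i %in% ring) s <- paste0(s, "1")
    kids <- children[[i]]
    if (length(kids) == 0L) return(s)
    sub <- vapply(kids, emit, character(1))
    if (length(sub) > 1L) {
      s <- paste0(s, paste0("(", sub[-length(sub)], ")", collapse = ""))
    }
    paste0(s, sub[length(sub)])
  }
  emit(1L)
}

tree_distance <- function(a, b, parent, depth) {
  d <- 0L
  while (a != b) {
    if (depth[a] < depth[b]) { b <- parent[b] } else { a <- parent[a] }
    d <- d + 1L
  }
  d
}

#' Generate a set of unique, valid synthetic SMILES
#'
#' Molecules are assembled in seeded batches, validated and canonicalized by
#' the chemistry toolkit, de-duplicated on canonical form, and returned in
#' generation order.  The run errors (reporting the yield) if the requested
#' count cannot be reached in a bounded number of attempts, which in practice
#' only happens when the spec's alphabet/size box contains fewer distinct
#' molecules than requested.
#'
#' @param spec A [synthetic_spec()].
#' @return Character vector of `spec$n_molecules` unique canonical SMILES.
#' @examples
#' \dontrun{
#' smi <- generate_synthetic_smiles(synthetic_spec(100, seed = 7))
#' all(smiles_is_valid(smi))  # TRUE
#' }
#' @export
generate_synthetic_smiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    found <- character(0)
    attempts <- 0L
    max_attempts <- max(200L, 40L * spec$n_molecules)
    while (length(found) < spec$n_molecules && attempts < max_attempts) {
      batch_n <- min(max(64L, 2L * (spec$n_molecules - length(found))),
                     max_attempts - attempts)
      raw <- vapply(seq_len(batch_n), function(i) random_molecule_smiles(spec),
                    character(1))
      attempts <- attempts + batch_n
      canon <- canonicalize(raw)
      canon <- canon[!is.na(canon) & nchar(canon) <= spec$max_smiles_len]
      found <- unique(c(found, canon))
    }
    if (length(found) < spec$n_molecules) {
      abort(sprintf(
        "generator yielded only %d of %d unique valid molecules in %d attempts",
        length(found), spec$n_molecules, attempts))
    }
    found[seq_len(spec$n_molecules)]
  })
}

# Reference drug structures, transcribed from their standard published
# canonical forms.  "table1_inhibitors": clozapine plus the eight molecules
# reported to inhibit transporter-mediated clozapine uptake.
# "fig5_comparators": clozapine plus drugs highlighted as latent-space
# neighbours of clozapine (antipsychotics, antihistamines, one COX inhibitor).
BUNDLED_SETS <- list(
  table1_inhibitors = c(
    clozapine      = "CN1CCN(CC1)C1=Nc2cc(Cl)ccc2Nc2ccccc21",
    olanzapine     = "CN1CCN(CC1)C1=Nc2ccccc2Nc2sc(C)cc21",
    chlorpromazine = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    quetiapine     = "OCCOCCN1CCN(CC1)C1=Nc2ccccc2Sc2ccccc21",
    prazosin       = "COc1cc2nc(N3CCN(C(=O)c4ccco4)CC3)nc(N)c2cc1OC",
    lamotrigine    = "Nc1nnc(-c2cccc(Cl)c2Cl)c(N)n1",
    indatraline    = "CNC1CC(c2ccc(Cl)c(Cl)c2)c2ccccc21",
    verapamil      = "COc1ccc(CCN(C)CCCC(C#N)(c2ccc(OC)c(OC)c2)C(C)C)cc1OC",
    rhein          = "O=C(O)c1cc(O)c2c(c1)C(=O)c1cccc(O)c1C2=O"
  ),
  fig5_comparators = c(
    clozapine   = "CN1CCN(CC1)C1=Nc2cc(Cl)ccc2Nc2ccccc21",
    loxapine    = "CN1CCN(CC1)C1=Nc2ccccc2Oc2ccc(Cl)cc21",
    mirtazapine = "CN1CCN2c3ccccc3Cc3cccnc3C2C1",
    quetiapine  = "OCCOCCN1CCN(CC1)C1=Nc2ccccc2Sc2ccccc12",
    ketotifen   = "CN1CCC(=C2c3ccccc3CC(=O)c3sccc32)CC1",
    alcaftadine = "CN1CCC(=C2c3ccccc3CCn3c(C=O)cnc32)CC1",
    ketorolac   = "O=C(O)C1CCn2c1ccc2C(=O)c1ccccc1"
  )
)

#' Load a bundled reference drug set
#'
#' @param name `"table1_inhibitors"` (clozapine plus the eight reported
#'   inhibitors of its transporter-mediated uptake) or `"fig5_comparators"`
#'   (clozapine plus structurally related comparator drugs).
#' @return A tibble with columns `id` and `smiles`.
#' @export
load_bundled_set <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(BUNDLED_SETS)) {
    abort(sprintf("unknown bundled set; available: %s",
                  paste(names(BUNDLED_SETS), collapse = ", ")))
  }
  set <- BUNDLED_SETS[[name]]
  tibble(id = names(set), smiles = unname(set))
}

#' Read molecules from a .smi or CSV file
#'
#' `.smi` files hold one SMILES per line, optionally followed by a
#' whitespace-separated identifier.  CSV files must carry `id` and `smiles`
#' columns.  Molecules missing an identifier are numbered `mol_00001`, ...
#'
#' @param path File path; format inferred from the extension (`.csv` vs
#'   anything else treated as `.smi`).
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(df))) {
      abort("CSV must have columns 'id' and 'smiles'")
    }
    return(tibble(id = as.character(df$id), smiles = df$smiles))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[[`, "", 1L)
  id <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else NA_character_, "")
  if (anyNA(id)) id[is.na(id)] <- sprintf("mol_%05d", which(is.na(id)))
  tibble(id = id, smiles = smiles)
}

#' Write molecules to a .smi file
#'
#' @param mols Tibble with columns `id` and `smiles` (or a character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(mols, path) {
  if (is.character(mols)) {
    mols <- tibble(id = sprintf("mol_%05d", seq_along(mols)), smiles = mols)
  }
  stopifnot(all(c("id", "smiles") %in% names(mols)))
  writeLines(paste(mols$smiles, mols$id), path)
  invisible(path)
}
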