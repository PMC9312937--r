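# Reading/writing protein structures in PDB format behind a uniform,
# backbone-centric model. Parsing is delegated to bio3d; the wrapper enforces
# the pipeline's contracts: first model only, polymer ATOM records only,
# highest-occupancy altloc, and a source tag distinguishing experimental
# structures (crystallographic B-factors) from predicted ones (pLDDT in the
# B-factor column, as in AlphaFold Database files).

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

#' Construct a protein structure object
#'
#' The in-memory model used throughout the pipeline: a flat atom table plus a
#' structure id and a source tag. Residues are identified by
#' `(chain, seq_id)` where `seq_id` is the author residue number pasted with
#' any insertion code; `res_idx` is a contiguous 1-based index in file order
#' within the whole structure.
#'
#' @param id free-text structure identifier.
#' @param source `"experimental"` or `"predicted"`. For predicted structures
#'   the B-factor column is interpreted as pLDDT in \[0, 100\].
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `seq_id`,
#'   `res_idx`, `aa`, `resid`, `elety`, `x`, `y`, `z`, `b`, `o`, `alt`.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(id, source = c("experimental", "predicted"), atoms) {
  source <- match.arg(source)
  needed <- c("chain", "resno", "insert", "seq_id", "res_idx", "aa", "resid",
              "elety", "x", "y", "z", "b", "o", "alt")
  if (!all(needed %in% names(atoms))) {
    stop("atom table is missing columns: ",
         paste(setdiff(needed, names(atoms)), collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  key <- paste(atoms$chain, atoms$seq_id, atoms$elety, atoms$alt)
  if (anyDuplicated(key)) stop("duplicate (chain, seq_id, atom, altloc) records")
  structure(list(id = id, source = source, atoms = atoms),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  r <- residues(x)
  cat(sprintf("<protein_structure> %s [%s]: %d chain(s), %d residues, %d atoms\n",
              x$id, x$source, length(unique(x$atoms$chain)), nrow(r),
              nrow(x$atoms)))
  invisible(x)
}

#' Per-residue table of a structure
#'
#' @param s a `protein_structure`.
#' @return data.frame with one row per residue: `chain`, `seq_id`, `resno`,
#'   `insert`, `aa`, `res_idx` and `complete` (TRUE when N, CA and C are all
#'   present).
#' @export
residues <- function(s) {
  a <- s$atoms
  first <- !duplicated(a$res_idx)
  r <- data.frame(chain = a$chain[first], seq_id = a$seq_id[first],
                  resno = a$resno[first], insert = a$insert[first],
                  aa = a$aa[first], res_idx = a$res_idx[first],
                  stringsAsFactors = FALSE)
  has <- function(nm) a$res_idx[a$elety == nm]
  r$complete <- r$res_idx %in% has("N") & r$res_idx %in% has("CA") &
    r$res_idx %in% has("C")
  r[order(r$res_idx), , drop = FALSE]
}

# n_res x 3 coordinate matrix for one backbone atom type (NA rows if missing).
atom_coords <- function(s, elety, res_table = residues(s)) {
  a <- s$atoms[s$atoms$elety == elety, , drop = FALSE]
  m <- matrix(NA_real_, nrow(res_table), 3L)
  i <- match(a$res_idx, res_table$res_idx)
  ok <- !is.na(i)
  m[i[ok], ] <- as.matrix(a[ok, c("x", "y", "z")])
  m
}

#' Read a protein structure from a PDB file
#'
#' Reads polymer `ATOM` records of the first model only. `HETATM` records
#' (including waters and ligands) are dropped. When a residue carries
#' alternate conformations, the highest-occupancy altloc is kept (ties break
#' to the alphabetically first altloc id). Nonstandard polymer residues are
#' retained with one-letter code `X`.
#'
#' @param path path to a PDB file.
#' @param source_tag `"experimental"` or `"predicted"`.
#' @param id structure id; defaults to the file base name.
#' @return a [protein_structure()].
#' @export
read_structure <- function(path, source_tag = c("experimental", "predicted"),
                           id = sub("\\.pdb$", "", basename(path))) {
  source_tag <- match.arg(source_tag)
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  if (!any(is_atom)) stop("empty structure: no ATOM records in ", path)
  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) {
    lines <- lines[seq_len(endmdl[1L] - 1L)]
    is_atom <- is_atom[seq_len(endmdl[1L] - 1L)]
    if (!any(is_atom)) stop("empty structure: no ATOM records in model 1 of ", path)
  }
  # fixed-column validation of the numeric fields bio3d would silently coerce
  for (ln in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz)) {
      stop(sprintf("malformed ATOM record at line %d of %s", ln, path))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!nrow(a)) stop("empty structure: no polymer ATOM records in ", path)
  a$alt[is.na(a$alt)] <- ""
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  # altloc resolution: within each residue/atom, keep highest occupancy,
  # ties to the alphabetically first altloc; file order restored afterwards
  a$.row <- seq_len(nrow(a))
  ord <- order(a$chain, a$resno, a$insert, a$elety, -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), , drop = FALSE]
  a <- a[order(a$.row), , drop = FALSE]
  a$.row <- NULL
  seq_id <- paste0(a$resno, a$insert)
  rk <- paste(a$chain, seq_id)
  res_idx <- match(rk, unique(rk))
  aa <- unname(.aa3to1[a$resid])
  aa[is.na(aa)] <- "X"
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      seq_id = seq_id, res_idx = res_idx, aa = aa,
                      resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z, b = a$b, o = a$o,
                      alt = a$alt, stringsAsFactors = FALSE)
  protein_structure(id = id, source = source_tag, atoms = atoms)
}

#' Write a protein structure as a PDB file
#'
#' Emits fixed-column `ATOM` records with serial numbers renumbered from 1.
#' Coordinates are preserved to 3 decimals and B-factors to 2 on a
#' read/write round trip.
#'
#' @param s a [protein_structure()] with at least one residue.
#' @param path output file path.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  if (!nrow(a)) stop("cannot write an empty structure")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$o, b = a$b)
  invisible(path)
}

#' Per-residue mean pLDDT profile of a predicted structure
#'
#' AlphaFold-style models store pLDDT (0-100) in the B-factor column of every
#' atom; this averages it per residue.
#'
#' @param s a predicted-source [protein_structure()].
#' @return data.frame with `chain`, `seq_id`, `res_idx` and `plddt`.
#' @export
plddt_profile <- function(s) {
  if (s$source != "predicted") {
    stop("plddt_profile expects a predicted structure; ",
         "experimental B-factors are not pLDDT values")
  }
  a <- s$atoms
  if (any(a$b > 100)) {
    warning("some atom B-factors exceed 100; not valid pLDDT values")
  }
  v <- tapply(a$b, a$res_idx, mean)
  first <- !duplicated(a$res_idx)
  data.frame(chain = a$chain[first], seq_id = a$seq_id[first],
             res_idx = a$res_idx[first], plddt = as.numeric(v[as.character(a$res_idx[first])]),
             stringsAsFactors = FALSE)
}

#' Build a structure from per-residue backbone matrices
#'
#' Convenience constructor used by the synthetic generator and by test
#' fixtures: wraps [build_backbone()] output (N, CA, C, O per residue) into a
#' [protein_structure()]. `bfac` is per-residue and recycled over atoms.
#'
#' @param bb list of N/CA/C/O coordinate matrices.
#' @param id structure id.
#' @param source `"experimental"` or `"predicted"`.
#' @param chain chain id.
#' @param aa per-residue one-letter codes (default poly-Ala).
#' @param bfac per-residue B-factor / pLDDT values.
#' @param resno_start first author residue number.
#' @return a [protein_structure()].
#' @export
structure_from_backbone <- function(bb, id, source = "experimental",
                                    chain = "A", aa = NULL, bfac = NULL,
                                    resno_start = 1L) {
  n <- nrow(bb$N)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(bfac)) bfac <- rep(0, n)
  stopifnot(length(aa) == n, length(bfac) == n)
  names_per_res <- c("N", "CA", "C", "O")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    rows[[i]] <- data.frame(chain = chain, resno = resno_start + i - 1L,
                            insert = "", seq_id = as.character(resno_start + i - 1L),
                            res_idx = i, aa = aa[i],
                            resid = unname(.aa1to3[aa[i]]),
                            elety = names_per_res,
                            x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                            b = bfac[i], o = 1, alt = "",
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$resid[is.na(atoms$resid)] <- "UNK"
  protein_structure(id = id, source = source, atoms = atoms)
}
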