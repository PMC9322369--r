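# The coarse-grained structure type: explicit backbone atoms (N, CA, C, O,
# optional amide H) plus one united side-chain particle per non-glycine
# residue. Stored as a flat data frame so that morphing and energy code can
# operate on coordinate columns directly.

.COORD_COLS <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
                 "c_x", "c_y", "c_z", "o_x", "o_y", "o_z",
                 "h_x", "h_y", "h_z", "sc_x", "sc_y", "sc_z")

.new_cg <- function(residues, label = "") {
  residues <- residues[order(residues$chain, residues$resno,
                             residues$icode), , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(residues = residues, label = label), class = "cg_structure")
}

.residue_key <- function(r) paste(r$chain, r$resno, r$icode, sep = "|")

#' All particle coordinates of a CG structure
#'
#' Stacks backbone atoms and side particles into one matrix (rows with
#' missing atoms are dropped). Used for grid exclusion, bounding boxes and
#' burial counts.
#' @param cg a `cg_structure`
#' @return numeric matrix with columns x, y, z
#' @export
cg_particles <- function(cg) {
  r <- cg$residues
  out <- matrix(numeric(0), 0, 3)
  if (is.null(r) || nrow(r) == 0) {
    colnames(out) <- c("x", "y", "z")
    return(out)
  }
  for (p in c("n", "ca", "c", "o", "h", "sc")) {
    m <- cbind(r[[paste0(p, "_x")]], r[[paste0(p, "_y")]],
               r[[paste0(p, "_z")]])
    out <- rbind(out, m[stats::complete.cases(m), , drop = FALSE])
  }
  colnames(out) <- c("x", "y", "z")
  out
}

.validate_cg <- function(cg) {
  r <- cg$residues
  if (nrow(r) == 0) return(invisible(cg))
  if (anyDuplicated(.residue_key(r)) > 0) {
    stop("duplicate residue keys in CG structure", call. = FALSE)
  }
  gly <- r$name == "GLY"
  if (any(gly & !is.na(r$sc_x))) {
    stop("GLY residues must not carry a side particle", call. = FALSE)
  }
  if (any(!gly & is.na(r$sc_x))) {
    stop("non-GLY residue without side particle: ",
         paste(.residue_key(r)[!gly & is.na(r$sc_x)], collapse = ", "),
         call. = FALSE)
  }
  p <- cg_particles(cg)
  if (nrow(p) > 1) {
    d <- stats::dist(p)
    if (min(d) < 0.01) {
      stop("degenerate coordinates: two particles closer than 0.01 A",
           call. = FALSE)
    }
  }
  invisible(cg)
}

#' @export
print.cg_structure <- function(x, ...) {
  r <- x$residues
  n_ion <- sum(r$klass == "ionizable")
  cat("CG structure", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ":", nrow(r), "residues,", n_ion, "ionizable\n")
  invisible(x)
}

.assign_class <- function(name, config) {
  kl <- config$residue_class[name]
  if (any(is.na(kl))) {
    stop("residue type(s) not in residue-class table: ",
         paste(unique(name[is.na(kl)]), collapse = ", "), call. = FALSE)
  }
  sign <- ifelse(kl == "ionizable", config$ionizable_sign[name], 0L)
  pka <- ifelse(kl == "ionizable", config$pka_water[name], NA_real_)
  if (any(kl == "ionizable" & (is.na(pka) | pka < 0 | pka > 14))) {
    stop("missing or out-of-range water pKa for an ionizable residue type",
         call. = FALSE)
  }
  list(klass = unname(kl), sign = as.integer(sign), pka = unname(pka))
}

#' Map an all-atom model to the coarse-grained representation
#'
#' Backbone atoms N, CA, C, O (and the amide H when present) are kept
#' explicitly; all side-chain heavy atoms (CB and beyond) are replaced by
#' their geometric centroid, the united side-chain particle. Glycine gets
#' no side particle. Residue class (nonpolar / polar / ionizable), charge
#' sign and intrinsic water pKa are assigned from the tables in `config`.
#'
#' @param model an [read_pdb_model()] result
#' @param config an [energy_config()]
#' @return an object of class `cg_structure`
#' @export
#' @examples
#' pdb <- system.file("extdata", "two_residues.pdb", package = "memcg")
#' cg <- coarse_grain(read_pdb_model(pdb), energy_config())
#' cg$residues$name
coarse_grain <- function(model, config = energy_config()) {
  stopifnot(inherits(model, "aa_model"))
  at <- model$atoms
  key <- paste(at$chain, at$resno, at$icode, sep = "|")
  ukey <- unique(key)
  n <- length(ukey)
  res <- data.frame(chain = character(n), resno = integer(n),
                    icode = character(n), name = character(n),
                    stringsAsFactors = FALSE)
  for (cc in .COORD_COLS) res[[cc]] <- NA_real_
  chain_of <- function(k) strsplit(k, "|", fixed = TRUE)[[1]]
  is_h <- grepl("^[0-9]*H", at$elety)
  for (i in seq_len(n)) {
    idx <- which(key == ukey[i])
    a <- at[idx, , drop = FALSE]
    res$chain[i] <- a$chain[1]
    res$resno[i] <- a$resno[1]
    res$icode[i] <- a$icode[1]
    res$name[i] <- a$resid[1]
    grab <- function(nm) {
      j <- which(a$elety == nm)[1]
      if (is.na(j)) NULL else c(a$x[j], a$y[j], a$z[j])
    }
    bb <- list(n = grab("N"), ca = grab("CA"), c = grab("C"), o = grab("O"),
               h = grab("H"))
    last_in_chain <- i == n || chain_of(ukey[min(i + 1, n)])[1] != a$chain[1]
    missing_bb <- c("N", "CA", "C", "O")[vapply(bb[c("n", "ca", "c", "o")],
                                                is.null, logical(1))]
    if ("O" %in% missing_bb && last_in_chain) {
      missing_bb <- setdiff(missing_bb, "O")
    }
    if (length(missing_bb) > 0) {
      stop("residue ", gsub("\\|", " ", ukey[i]), " (", a$resid[1],
           ") is missing backbone atom(s): ",
           paste(missing_bb, collapse = ", "), call. = FALSE)
    }
    for (p in names(bb)) {
      if (!is.null(bb[[p]])) {
        res[i, paste0(p, c("_x", "_y", "_z"))] <- bb[[p]]
      }
    }
    side <- a[!(a$elety %in% .BACKBONE_ATOMS) & !is_h[idx], , drop = FALSE]
    if (res$name[i] != "GLY") {
      if (nrow(side) > 0) {
        res[i, c("sc_x", "sc_y", "sc_z")] <-
          c(mean(side$x), mean(side$y), mean(side$z))
      } else {
        # incomplete side chain in the input: place a pseudo particle along
        # the local pseudo-CB direction at the residue-type distance
        warning("residue ", gsub("\\|", " ", ukey[i]),
                " has no side-chain atoms; placing a pseudo side particle")
        res[i, c("sc_x", "sc_y", "sc_z")] <-
          .pseudo_side(bb$n, bb$ca, bb$c,
                       .side_dist_of(res$name[i], config))
      }
    }
  }
  cls <- .assign_class(res$name, config)
  res$klass <- cls$klass
  res$sign <- cls$sign
  res$pka_water <- cls$pka
  cg <- .new_cg(res, label = model$source)
  .validate_cg(cg)
  cg
}

.side_dist_of <- function(name, config) {
  d <- config$side_dist[name]
  if (is.na(d)) d <- 2.5
  unname(d)
}

# direction opposite the mean of the CA->N and CA->C bonds: roughly the
# C-beta direction of an L-amino acid backbone
.pseudo_side <- function(n, ca, c, dist) {
  v <- -((n - ca) + (c - ca))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) v <- c(0, 0, 1) else v <- v / nv
  ca + dist * v
}

#' Mutate one residue of a CG structure
#'
#' Replaces the residue type at `key`, updating class, charge sign and
#' water pKa from the tables in `config`. The side-particle coordinate is
#' retained (a mutation to GLY removes it; a mutation from GLY places a
#' pseudo particle along the local pseudo-CB direction). All other
#' residues are untouched.
#'
#' @param cg a `cg_structure`
#' @param key residue key: list or vector `(chain, resno)` or
#'   `(chain, resno, icode)`
#' @param new_name 3-letter residue type present in the residue-class table
#' @param config an [energy_config()]
#' @return a modified copy of `cg`
#' @export
mutate_residue <- function(cg, key, new_name, config = energy_config()) {
  stopifnot(inherits(cg, "cg_structure"))
  key <- as.list(key)
  if (length(key) == 2) key <- c(key, "")
  if (!new_name %in% names(config$residue_class)) {
    stop("unknown residue type: ", new_name, call. = FALSE)
  }
  r <- cg$residues
  i <- which(r$chain == key[[1]] & r$resno == as.integer(key[[2]]) &
               r$icode == key[[3]])
  if (length(i) != 1) {
    stop("no residue with key ", paste(unlist(key), collapse = " "),
         call. = FALSE)
  }
  old_name <- r$name[i]
  r$name[i] <- new_name
  cls <- .assign_class(new_name, config)
  r$klass[i] <- cls$klass
  r$sign[i] <- cls$sign
  r$pka_water[i] <- cls$pka
  if (new_name == "GLY") {
    r[i, c("sc_x", "sc_y", "sc_z")] <- NA_real_
  } else if (old_name == "GLY") {
    r[i, c("sc_x", "sc_y", "sc_z")] <- .pseudo_side(
      c(r$n_x[i], r$n_y[i], r$n_z[i]),
      c(r$ca_x[i], r$ca_y[i], r$ca_z[i]),
      c(r$c_x[i], r$c_y[i], r$c_z[i]),
      .side_dist_of(new_name, config))
  }
  out <- .new_cg(r, label = cg$label)
  .validate_cg(out)
  out
}

#' Match residues between two CG structures
#'
#' Pairs residues with identical keys (chain, number, insertion code) and
#' identical residue names; a `mutations` map (named character vector,
#' names are `"chain|resno|icode"` keys) declares name changes that should
#' still pair. Unmatched residues of either structure are listed.
#'
#' @param a,b `cg_structure` objects
#' @param mutations optional named character vector of declared mutations
#' @return a list with `pairs` (2-column integer matrix of row indices into
#'   `a` and `b`), `unmatched_a`, `unmatched_b`
#' @export
match_residues <- function(a, b, mutations = NULL) {
  ka <- .residue_key(a$residues)
  kb <- .residue_key(b$residues)
  ia <- match(ka, kb)
  ok <- !is.na(ia)
  same_name <- rep(FALSE, length(ka))
  same_name[ok] <- a$residues$name[ok] == b$residues$name[ia[ok]] |
    ka[ok] %in% names(mutations %||% character(0))
  ok <- ok & same_name
  pairs <- cbind(a = which(ok), b = ia[ok])
  list(pairs = pairs,
       unmatched_a = setdiff(seq_along(ka), pairs[, 1]),
       unmatched_b = setdiff(seq_along(kb), pairs[, 2]))
}

#' Apply a rigid transform to a CG structure
#'
#' @param cg a `cg_structure`
#' @param rotation 3x3 rotation matrix (default identity)
#' @param translation length-3 translation vector (default zero)
#' @return the transformed structure
#' @export
transform_cg <- function(cg, rotation = diag(3), translation = c(0, 0, 0)) {
  r <- cg$residues
  for (p in c("n", "ca", "c", "o", "h", "sc")) {
    cols <- paste0(p, c("_x", "_y", "_z"))
    m <- as.matrix(r[, cols])
    keep <- stats::complete.cases(m)
    if (any(keep)) {
      m[keep, ] <- t(rotation %*% t(m[keep, , drop = FALSE]) + translation)
      r[, cols] <- m
    }
  }
  .new_cg(r, label = cg$label)
}
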