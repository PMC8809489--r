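# Symmetry operations in the fractional basis, plus a small table of common
# space-group settings so CIFs that give only a Hermann-Mauguin symbol can be
# expanded. Explicit operation lists in a CIF always take precedence.

#' Construct a symmetry operation
#'
#' @param rotation 3x3 integer-valued matrix acting on fractional coordinates.
#' @param translation fractional translation 3-vector.
#' @return An object of class `symop`.
#' @export
symop <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3) ps_symmetry_error("translation must have length 3")
  d <- det(rotation)
  if (abs(abs(d) - 1) > 1e-8) {
    ps_symmetry_error("symmetry rotation must have determinant +/- 1")
  }
  structure(list(rotation = rotation, translation = translation %% 1),
            class = "symop")
}

#' Identity symmetry operation
#' @return The identity `symop` (x, y, z).
#' @export
identity_symop <- function() symop(diag(3), c(0, 0, 0))

#' Apply a symmetry operation to fractional coordinates
#'
#' @param op a [symop()].
#' @param frac 3-vector or n x 3 matrix of fractional coordinates.
#' @param reduce reduce the result to `[0, 1)`?
#' @return Transformed fractional coordinates.
#' @export
apply_symop <- function(op, frac, reduce = TRUE) {
  stopifnot(inherits(op, "symop"))
  out <- if (is.matrix(frac)) {
    sweep(t(op$rotation %*% t(frac)), 2, op$translation, `+`)
  } else {
    as.numeric(op$rotation %*% frac) + op$translation
  }
  if (reduce) out <- out - floor(out)
  out
}

.parse_frac_number <- function(s) {
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    as.numeric(parts[1]) / as.numeric(parts[2])
  } else {
    as.numeric(s)
  }
}

#' Parse a symmetry operation from xyz notation
#'
#' Accepts strings such as `"x, y, z"`, `"-x, y+1/2, -z"` or `"1/2+x, -y, z"`.
#'
#' @param xyz a single string.
#' @return A [symop()].
#' @export
parse_symop <- function(xyz) {
  s <- tolower(gsub("[ '\"]", "", xyz))
  comps <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(comps) != 3) ps_symmetry_error(paste0("cannot parse symmetry op: ", xyz))
  rot <- matrix(0, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    toks <- regmatches(comps[i], gregexpr("[+-]?[^+-]+", comps[i]))[[1]]
    if (!length(toks)) ps_symmetry_error(paste0("cannot parse symmetry op: ", xyz))
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (grepl("[xyz]", body)) {
        var <- regmatches(body, regexpr("[xyz]", body))
        j <- match(var, c("x", "y", "z"))
        coef <- sub("\\*?[xyz]", "", body)
        coefv <- if (nzchar(coef)) .parse_frac_number(sub("\\*$", "", coef)) else 1
        if (is.na(coefv)) ps_symmetry_error(paste0("cannot parse symmetry op: ", xyz))
        rot[i, j] <- rot[i, j] + sign * coefv
      } else {
        val <- .parse_frac_number(body)
        if (is.na(val)) ps_symmetry_error(paste0("cannot parse symmetry op: ", xyz))
        tr[i] <- tr[i] + sign * val
      }
    }
  }
  symop(rot, tr)
}

#' Render a symmetry operation in xyz notation
#'
#' @param op a [symop()].
#' @return A string such as `"-x,y+1/2,-z"`.
#' @export
symop_to_xyz <- function(op) {
  stopifnot(inherits(op, "symop"))
  vars <- c("x", "y", "z")
  comps <- character(3)
  for (i in 1:3) {
    terms <- character(0)
    for (j in 1:3) {
      cij <- op$rotation[i, j]
      if (abs(cij) > 1e-9) {
        pre <- if (cij < 0) "-" else if (length(terms)) "+" else ""
        mag <- if (abs(abs(cij) - 1) < 1e-9) "" else format(abs(cij))
        terms <- c(terms, paste0(pre, mag, vars[j]))
      }
    }
    t_i <- op$translation[i] %% 1
    if (t_i > 1e-9 && t_i < 1 - 1e-9) {
      frac <- .as_simple_fraction(t_i)
      terms <- c(terms, paste0("+", frac))
    }
    comps[i] <- paste(terms, collapse = "")
  }
  paste(comps, collapse = ",")
}

.as_simple_fraction <- function(x) {
  for (den in c(2, 3, 4, 6, 8, 12)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(paste0(round(num), "/", den))
  }
  format(x)
}

# Common molecular-crystal space-group settings (standard settings; unique
# axis b for monoclinic). Keys are normalized Hermann-Mauguin symbols with
# spaces removed.
.spacegroup_table <- list(
  "p1" = c("x,y,z"),
  "p-1" = c("x,y,z", "-x,-y,-z"),
  "p21" = c("x,y,z", "-x,y+1/2,-z"),
  "pc" = c("x,y,z", "x,-y,z+1/2"),
  "c2" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "cc" = c("x,y,z", "x,-y,z+1/2", "x+1/2,y+1/2,z", "x+1/2,-y+1/2,z+1/2"),
  "p21/c" = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
  "p21/m" = c("x,y,z", "-x,y+1/2,-z", "-x,-y,-z", "x,-y+1/2,z"),
  "c2/c" = c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
             "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2",
             "-x+1/2,-y+1/2,-z", "x+1/2,-y+1/2,z+1/2"),
  "p212121" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "pca21" = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y,z", "-x+1/2,y,z+1/2"),
  "pna21" = c("x,y,z", "-x,-y,z+1/2", "x+1/2,-y+1/2,z", "-x+1/2,y+1/2,z+1/2"),
  "pbca" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z",
             "-x,-y,-z", "x+1/2,y,-z+1/2", "x,-y+1/2,z+1/2", "-x+1/2,y+1/2,z"),
  "pbcn" = c("x,y,z", "-x+1/2,-y+1/2,z+1/2", "-x,y,-z+1/2", "x+1/2,-y+1/2,-z",
             "-x,-y,-z", "x+1/2,y+1/2,-z+1/2", "x,-y,z+1/2", "-x+1/2,y+1/2,z")
)

#' Symmetry operations for a Hermann-Mauguin space-group symbol
#'
#' Resolves a small table of space-group settings common in molecular
#' crystallography. Symbols are matched after removing spaces and
#' parenthesised screw-axis notation (`P2(1)` == `P21`).
#'
#' @param symbol Hermann-Mauguin symbol, e.g. `"P21/c"`.
#' @return List of [symop()]s, identity first.
#' @export
spacegroup_ops <- function(symbol) {
  key <- tolower(gsub("[ ()_]", "", symbol))
  ops <- .spacegroup_table[[key]]
  if (is.null(ops)) {
    ps_symmetry_error(paste0("space-group symbol not in bundled table: ", symbol))
  }
  lapply(ops, parse_symop)
}
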