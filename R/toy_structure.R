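# Programmatic toy structures for exercising the surface-exposure rule
# without downloading a deposited structure.

AA1_TO_3 <- setNames(names(AA3_TO_1), unname(AA3_TO_1))

# ~evenly distributed points on a unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (k - 0.5)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Build a synthetic extended-chain structure
#'
#' Places an idealized extended chain (backbone N, CA, C, O plus CB for
#' non-glycine residues; CA spacing 3.8 A along the x axis). Residues
#' flagged `buried` are enclosed in a sealed spherical shell of dummy
#' carbon atoms (HETATM `DUM`, chain Z) dense enough that no probe-sized
#' sphere point escapes, driving their accessibility ratio to ~0.
#' The output parses as standard PDB via [write_pdb()].
#'
#' @param residues Character vector of one-letter residue codes, or a
#'   single string.
#' @param buried Logical vector (recycled) flagging residues to
#'   enclose; default all exposed.
#' @param shell_radius Shell radius in Angstrom around the residue CA
#'   (default 4).
#' @param shell_points Dummy atoms per shell (default 350).
#' @param ca_spacing CA-CA spacing along the chain axis in Angstrom.
#'   The default 3.8 is the ideal extended-chain spacing; a burial
#'   shell then also shadows the chain neighbours of the enclosed
#'   residue (as in a real structure). Fixtures that need burial
#'   confined to the flagged residues should widen the chain (e.g.
#'   `ca_spacing = 9`), which keeps residues sterically independent.
#' @return Object of class `toy_structure` (list with an `atoms` data
#'   frame).
#' @export
make_toy_structure <- function(residues, buried = FALSE,
                               shell_radius = 4, shell_points = 350L,
                               ca_spacing = 3.8) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(residues)
  if (!all(residues %in% names(AA1_TO_3))) {
    stop("unknown residue code(s): ",
         paste(setdiff(residues, names(AA1_TO_3)), collapse = ", "))
  }
  n <- length(residues)
  buried <- rep_len(as.logical(buried), n)

  rows <- list()
  add <- function(record, elety, resid, chain, resno, xyz, element) {
    rows[[length(rows) + 1L]] <<- data.frame(
      record = record, chain = chain, resno = resno, resid = resid,
      elety = elety, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n)) {
    ca <- c(ca_spacing * (i - 1L), 0, 0)
    res3 <- AA1_TO_3[[residues[i]]]
    add("ATOM", "N", res3, "A", i, ca + c(-0.80, 1.22, 0), "N")
    add("ATOM", "CA", res3, "A", i, ca, "C")
    add("ATOM", "C", res3, "A", i, ca + c(1.00, 1.14, 0), "C")
    add("ATOM", "O", res3, "A", i, ca + c(1.00, 2.37, 0), "O")
    if (residues[i] != "G") {
      add("ATOM", "CB", res3, "A", i, ca + c(0, -0.95, 1.20), "C")
    }
  }
  dum <- 0L
  for (i in which(buried)) {
    ca <- c(ca_spacing * (i - 1L), 0, 0)
    pts <- fibonacci_sphere(as.integer(shell_points)) * shell_radius
    for (k in seq_len(nrow(pts))) {
      dum <- dum + 1L
      add("HETATM", "C", "DUM", "Z", 9000L + dum, ca + pts[k, ], "C")
    }
  }
  structure(list(atoms = do.call(rbind, rows), residues = residues,
                 buried = buried),
            class = "toy_structure")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat("<toy_structure> ", length(x$residues), " residues (",
      sum(x$buried), " buried), ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Write a toy structure as a standard PDB file
#'
#' @param structure `toy_structure` from [make_toy_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "toy_structure"))
  at <- structure$atoms
  lines <- sprintf(
    "%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$record, seq_len(nrow(at)),
    ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
    at$resid, at$chain, at$resno, at$x, at$y, at$z, 1, 0, at$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
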