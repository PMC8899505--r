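# The composable descriptor language ("code objects"): named molecule and
# atom properties combined by operators. The text syntax mirrors the
# command-line syntax, e.g.
#   Combine (Weight, LogP, HbondDonor, HbondAcceptor)
#   Define [VeberDruglike = Less (lhs = LipinskiViolationsVeber, rhs = 1)]
#   2DASmoothSign (property = Atom_SigmaCharge)
# '(' '[' '{' are interchangeable, whitespace and newlines are ignored,
# keyword keys may contain spaces, and @file splices in a descriptor file.

#' Create a descriptor evaluation context
#'
#' Holds the aliases created by `Define` so that several descriptor strings
#' parsed against the same context can share definitions.
#' @return a `descriptor_context` environment.
#' @export
descriptor_context <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$aliases <- list()
  class(ctx) <- "descriptor_context"
  ctx
}

# ---- tokenizer --------------------------------------------------------------

descriptor_tokens <- function(text) {
  text <- paste(text, collapse = " ")
  # @file inclusion (repeated until none left; guarded against runaway depth)
  for (depth in 1:20) {
    hit <- regmatches(text, regexpr("@[^][(){},=[:space:]]+", text))
    if (!length(hit)) break
    path <- substring(hit, 2)
    if (!file.exists(path)) stop("descriptor @file not found: ", path)
    ins <- paste(readLines(path, warn = FALSE), collapse = " ")
    text <- sub(hit, ins, text, fixed = TRUE)
    if (depth == 20L) stop("descriptor @file inclusion too deep")
  }
  pat <- "[A-Za-z0-9_./\\\\%+-]+|[][(){},=]"
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # verify nothing but whitespace was skipped
  residue <- gsub(pat, "", text)
  if (grepl("[^[:space:]\"']", residue))
    stop("unexpected character(s) in descriptor text: ",
         sQuote(gsub("[[:space:]\"']", "", residue)))
  toks
}

is_open <- function(tok) tok %in% c("(", "[", "{")
is_close <- function(tok) tok %in% c(")", "]", "}")

# ---- parser -----------------------------------------------------------------

#' Parse a descriptor specification
#'
#' @param text descriptor text in the code-object grammar.
#' @param ctx a [descriptor_context()] collecting `Define` aliases; a fresh
#'   one is used when omitted.
#' @return a `descriptor_spec` tree. Several whitespace-separated top-level
#'   expressions are wrapped in `Combine`.
#' @export
parse_descriptor <- function(text, ctx = descriptor_context()) {
  toks <- descriptor_tokens(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    t <- take()
    if (is.na(t) || is_close(t) || t %in% c(",", "="))
      stop("descriptor parse error at token ", pos - 1L, ": unexpected ",
           sQuote(if (is.na(t)) "end of input" else t))
    num <- suppressWarnings(as.numeric(t))
    if (!is.na(num) && !is_open(peek()))
      return(structure(list(kind = "constant", value = num),
                       class = "descriptor_spec"))
    if (!is_open(peek()))
      return(structure(list(kind = "name", name = t),
                       class = "descriptor_spec"))
    take()  # opening bracket
    args <- list(); kwargs <- list()
    repeat {
      if (is.na(peek())) stop("descriptor parse error: unbalanced brackets")
      if (is_close(peek())) { take(); break }
      if (peek() == ",") { take(); next }
      # keyword? a run of bare name tokens followed by '='
      key <- character()
      save <- pos
      while (!is.na(peek()) && !is_open(peek()) && !is_close(peek()) &&
             !peek() %in% c(",", "=")) key <- c(key, take())
      if (identical(peek(), "=") && length(key)) {
        take()
        # keep the raw (case-preserving) key: Define aliases are case
        # sensitive; operator keys are matched case/space-insensitively
        kwargs[[paste(key, collapse = "")]] <- parse_expr()
      } else {
        pos <<- save
        args[[length(args) + 1L]] <- parse_expr()
      }
    }
    node <- structure(list(kind = "call", name = t, args = args,
                           kwargs = kwargs),
                      class = "descriptor_spec")
    if (t == "Define") register_alias(node, ctx)
    node
  }
  exprs <- list()
  while (!is.na(peek())) exprs[[length(exprs) + 1L]] <- parse_expr()
  if (!length(exprs)) stop("empty descriptor text")
  spec <- if (length(exprs) == 1L) exprs[[1L]]
          else structure(list(kind = "call", name = "Combine", args = exprs,
                              kwargs = list()),
                         class = "descriptor_spec")
  attr(spec, "context") <- ctx
  spec
}

normalize_key <- function(key) tolower(gsub("[ _]", "", key))

register_alias <- function(node, ctx) {
  if (length(node$kwargs) != 1L)
    stop("Define expects exactly one 'Alias = expression' pair")
  ctx$aliases[[names(node$kwargs)[1]]] <- node$kwargs[[1]]
  invisible(ctx)
}

#' @export
format.descriptor_spec <- function(x, ...) {
  switch(x$kind,
    constant = format(x$value),
    name = x$name,
    call = {
      parts <- c(vapply(x$args, format, character(1)),
                 if (length(x$kwargs))
                   paste0(names(x$kwargs), " = ",
                          vapply(x$kwargs, format, character(1))))
      paste0(x$name, "(", paste(parts, collapse = ", "), ")")
    })
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat("<descriptor>", format(x), "\n")
  invisible(x)
}

# ---- property registry ------------------------------------------------------

# built lazily so source order within the package does not matter
molecule_property_registry <- function() list(
  Weight = mol_weight,
  HbondDonor = hbond_donors,
  HbondAcceptor = hbond_acceptors,
  NRotBond = n_rotatable_bonds,
  NRings = n_rings,
  NAromaticRings = n_aromatic_rings,
  TopologicalPolarSurfaceArea = tpsa,
  LogP = log_p,
  LipinskiViolations = lipinski_violations,
  LipinskiViolationsVeber = lipinski_violations_veber,
  LipinskiDruglike = lipinski_druglike)

atomic_property_registry <- function() list(
  Atom_SigmaCharge = atom_sigma_charge,
  Atom_TopologicalPolarSurfaceArea = atom_tpsa,
  Atom_Mass = atom_mass)

# ---- evaluator --------------------------------------------------------------

#' Evaluate a descriptor on a molecule
#'
#' Deterministic and side-effect free: molecule properties yield length-1 (or
#' fixed-length) vectors, atomic properties one value per atom in atom-index
#' order, `Combine` concatenates.
#'
#' @param spec a `descriptor_spec` from [parse_descriptor()] (a character
#'   string is parsed on the fly).
#' @param mol a `molecule`.
#' @param ctx evaluation context; defaults to the context the spec was parsed
#'   in.
#' @return numeric vector.
#' @export
evaluate_descriptor <- function(spec, mol, ctx = NULL) {
  if (is.character(spec)) spec <- parse_descriptor(spec,
                                                   ctx %||% descriptor_context())
  ctx <- ctx %||% attr(spec, "context") %||% descriptor_context()
  eval_node(spec, mol, ctx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eval_node <- function(node, mol, ctx) {
  switch(node$kind,
    constant = node$value,
    name = eval_name(node$name, mol, ctx),
    call = eval_call(node, mol, ctx),
    stop("unknown descriptor node kind: ", node$kind))
}

eval_name <- function(name, mol, ctx) {
  if (!is.null(ctx$aliases[[name]])) return(eval_node(ctx$aliases[[name]], mol, ctx))
  molp <- molecule_property_registry()
  if (!is.null(molp[[name]])) return(as.numeric(molp[[name]](mol)))
  atp <- atomic_property_registry()
  if (!is.null(atp[[name]])) return(as.numeric(atp[[name]](mol)))
  # fall back to an MDL data-block property on the molecule
  if (!is.null(mol$properties[[name]])) {
    v <- suppressWarnings(as.numeric(strsplit(
      trimws(mol$properties[[name]]), "[,[:space:]]+")[[1]]))
    if (anyNA(v))
      stop("MDL property ", sQuote(name), " on molecule ",
           sQuote(mol$name), " is not numeric")
    return(v)
  }
  stop("property ", sQuote(name), " is undefined for molecule ",
       sQuote(mol$name))
}

get_kwarg <- function(node, key) {
  hit <- which(normalize_key(names(node$kwargs)) == normalize_key(key))
  if (length(hit)) node$kwargs[[hit[1]]] else NULL
}

eval_kwarg <- function(node, key, mol, ctx, default = NULL) {
  kw <- get_kwarg(node, key)
  if (is.null(kw)) {
    if (is.null(default)) stop(node$name, " requires '", key, "'")
    return(default)
  }
  eval_node(kw, mol, ctx)
}

eval_call <- function(node, mol, ctx) {
  name <- node$name
  args <- function() lapply(node$args, eval_node, mol = mol, ctx = ctx)
  elementwise <- function(f) {
    vals <- c(args(), lapply(node$kwargs, eval_node, mol = mol, ctx = ctx))
    if (length(vals) < 2L) stop(name, " needs at least two arguments")
    Reduce(function(a, b) {
      if (length(a) != length(b) && length(a) > 1L && length(b) > 1L)
        stop("arity mismatch in ", name)
      f(a, b)
    }, vals)
  }
  switch(name,
    Combine = as.numeric(unlist(args())),
    Define = numeric(0),
    Constant = as.numeric(unlist(args())),
    Multiply = elementwise(`*`),
    Add = elementwise(`+`),
    Subtract = elementwise(`-`),
    Less = {
      lhs <- eval_kwarg(node, "lhs", mol, ctx)
      rhs <- eval_kwarg(node, "rhs", mol, ctx)
      as.numeric(lhs < rhs)
    },
    Greater = {
      lhs <- eval_kwarg(node, "lhs", mol, ctx)
      rhs <- eval_kwarg(node, "rhs", mol, ctx)
      as.numeric(lhs > rhs)
    },
    GreaterEqual = {
      as.numeric(eval_kwarg(node, "lhs", mol, ctx) >=
                 eval_kwarg(node, "rhs", mol, ctx))
    },
    LessEqual = {
      as.numeric(eval_kwarg(node, "lhs", mol, ctx) <=
                 eval_kwarg(node, "rhs", mol, ctx))
    },
    Equal = {
      as.numeric(eval_kwarg(node, "lhs", mol, ctx) ==
                 eval_kwarg(node, "rhs", mol, ctx))
    },
    MoleculeSum = sum(one_arg(node, mol, ctx)),
    MoleculeMean = mean(one_arg(node, mol, ctx)),
    MoleculeMin = min(one_arg(node, mol, ctx)),
    MoleculeMax = max(one_arg(node, mol, ctx)),
    MoleculeSD = stats::sd(one_arg(node, mol, ctx)),
    `2DASmoothSign` = eval_autocorrelation(node, mol, ctx, mode = "bonds"),
    `3daSmoothSign` = eval_autocorrelation(node, mol, ctx, mode = "euclidean"),
    `3DASmoothSign` = eval_autocorrelation(node, mol, ctx, mode = "euclidean"),
    PredictionMean = eval_prediction(node, mol, ctx, metric = "Mean"),
    PredictionInfo = eval_prediction(node, mol, ctx, metric = NULL),
    stop("unknown descriptor operator: ", sQuote(name))
  )
}

one_arg <- function(node, mol, ctx) {
  if (length(node$args) != 1L)
    stop(node$name, " expects exactly one argument")
  eval_node(node$args[[1]], mol, ctx)
}

eval_autocorrelation <- function(node, mol, ctx, mode) {
  prop <- get_kwarg(node, "property")
  if (is.null(prop)) stop(node$name, " requires 'property ='")
  values <- eval_node(prop, mol, ctx)
  if (length(values) != n_atoms(mol))
    stop("autocorrelation property must be atomic (one value per atom)")
  n_bins <- as.integer(eval_kwarg(node, "steps", mol, ctx,
                                  default = if (mode == "bonds") 11L else 24L))
  width <- eval_kwarg(node, "stepsize", mol, ctx,
                      default = if (mode == "bonds") 1 else 0.25)
  if (mode == "euclidean" && all(coords(mol) == 0))
    stop("3D autocorrelation requires coordinates on molecule ",
         sQuote(mol$name))
  unname(autocorrelation(mol, values, mode = mode, bin_width = width,
                         n_bins = n_bins, signed = TRUE))
}
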