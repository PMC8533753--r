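#' Regulatory circuit data model
#'
#' An `emt_circuit` bundles the circuit topology (nodes and signed, typed
#' edges), the kinetic parameters (per-node basal production `g` and
#' degradation `k`; per-edge shifted-Hill threshold, Hill coefficient and
#' fold-change), an optional combinatorial-binding microRNA module for the
#' miR-200 --| ZEB interaction, and the external EMT-inducing signal node.
#' The signal enters the state vector as a clamped node (zero derivative)
#' acting on SNAIL production through an ordinary activating shifted-Hill
#' edge.
#'
#' @name emt_circuit
NULL

CIRCUIT_FILES <- c(
  control    = "circuit_control.yaml",
  klf4       = "circuit_klf4.yaml",
  klf4_cdh1  = "circuit_klf4_cdh1.yaml",
  grhl2_cdh1 = "circuit_grhl2_cdh1.yaml"
)

#' Load a circuit variant from its shipped configuration file
#'
#' Variants: `"control"` is the core EMT circuit (miR-200, ZEB mRNA/protein,
#' SNAIL, SLUG) driven by the external signal; `"klf4"` adds KLF4 and its
#' mutual inhibitions with SNAIL and SLUG; `"klf4_cdh1"` further appends
#' E-cadherin (CDH1) repressed by ZEB and SLUG; `"grhl2_cdh1"` replaces KLF4
#' by GRHL2 engaged in a toggle with ZEB.
#'
#' @param variant circuit variant name.
#' @param file optional path to a circuit YAML file overriding the shipped one.
#' @return an `emt_circuit` object.
#' @export
emt_circuit <- function(variant = c("klf4", "control", "klf4_cdh1", "grhl2_cdh1"),
                        file = NULL) {
  variant <- match.arg(variant)
  if (is.null(file)) {
    file <- system.file("extdata", CIRCUIT_FILES[[variant]], package = "emtdyn")
  }
  if (!nzchar(file) || !file.exists(file)) {
    stop("circuit configuration file not found: ", CIRCUIT_FILES[[variant]])
  }
  read_circuit(file)
}

#' Read a circuit from a YAML configuration file
#'
#' @param path path to a YAML file with `nodes`, `edges`, optional
#'   `mirna_module`, `signal` and `variant` blocks.
#' @return an `emt_circuit` object (validated).
#' @export
read_circuit <- function(path) {
  cfg <- yaml::read_yaml(path)
  nodes <- do.call(rbind, lapply(cfg$nodes, function(n) {
    data.frame(name = n$name, kind = n$kind, g = as.numeric(n$g),
               k = as.numeric(n$k), clamped = isTRUE(n$clamped),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(cfg$edges, function(e) {
    data.frame(source = e$source, target = e$target, sign = e$sign,
               mode = if (is.null(e$mode)) "transcriptional" else e$mode,
               threshold = as.numeric(e$threshold), hill = as.numeric(e$hill),
               lambda = as.numeric(e$lambda), stringsAsFactors = FALSE)
  }))
  mirna <- NULL
  if (!is.null(cfg$mirna_module)) {
    mm <- cfg$mirna_module
    mirna <- list(mir = mm$mir, mrna = mm$mrna, protein = mm$protein,
                  u0 = as.numeric(mm$u0), l = as.numeric(mm$l),
                  gamma_m = as.numeric(mm$gamma_m), gamma_u = as.numeric(mm$gamma_u))
  }
  circ <- structure(list(
    nodes = nodes, edges = edges, mirna = mirna,
    signal = list(node = cfg$signal$node, value = as.numeric(cfg$signal$value)),
    variant = if (is.null(cfg$variant)) "custom" else cfg$variant
  ), class = "emt_circuit")
  validate_circuit(circ)
  circ
}

#' Write a circuit to a YAML configuration file
#' @param circuit an `emt_circuit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(circuit, path) {
  stopifnot(inherits(circuit, "emt_circuit"))
  cfg <- list(
    variant = circuit$variant,
    signal = list(node = circuit$signal$node, value = circuit$signal$value),
    nodes = lapply(seq_len(nrow(circuit$nodes)), function(i) {
      n <- circuit$nodes[i, ]
      list(name = n$name, kind = n$kind, g = n$g, k = n$k, clamped = n$clamped)
    }),
    edges = lapply(seq_len(nrow(circuit$edges)), function(i) {
      e <- circuit$edges[i, ]
      list(source = e$source, target = e$target, sign = e$sign, mode = e$mode,
           threshold = e$threshold, hill = e$hill, lambda = e$lambda)
    })
  )
  if (!is.null(circuit$mirna)) cfg$mirna_module <- circuit$mirna
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate circuit invariants
#'
#' Checks that every edge endpoint is a declared node, that there are no
#' duplicate (source, target) pairs, that kinetic parameters are positive
#' (`g >= 0` for clamped input nodes), and that the fold-change is below 1 on
#' inhibitory edges and above 1 on activating ones.
#'
#' @param circuit an `emt_circuit`.
#' @return the circuit, invisibly; stops with a configuration error otherwise.
#' @export
validate_circuit <- function(circuit) {
  nd <- circuit$nodes; ed <- circuit$edges
  if (anyDuplicated(nd$name)) stop("duplicate node names")
  bad <- !(ed$source %in% nd$name) | !(ed$target %in% nd$name)
  if (any(bad)) stop("edge endpoint not declared as node: ",
                     paste(ed$source[bad], ed$target[bad], collapse = ", "))
  if (anyDuplicated(ed[, c("source", "target")])) stop("duplicate (source, target) edge")
  free <- !nd$clamped
  if (any(nd$g[free] <= 0) || any(nd$k[free] <= 0)) {
    stop("production and degradation rates must be positive for dynamic nodes")
  }
  if (any(!is.finite(ed$threshold)) || any(ed$threshold <= 0)) stop("edge thresholds must be > 0")
  if (any(ed$hill < 1)) stop("Hill coefficients must be >= 1")
  inh <- ed$sign == "inhibition"
  if (any(ed$lambda[inh] >= 1) || any(ed$lambda[inh] <= 0)) {
    stop("inhibitory fold-change must lie in (0, 1)")
  }
  if (any(ed$lambda[!inh] <= 1)) stop("activating fold-change must exceed 1")
  if (!circuit$signal$node %in% nd$name) stop("signal node not declared")
  if (circuit$signal$value < 0) stop("external signal level must be >= 0")
  invisible(circuit)
}

#' Set the external EMT-inducing signal level
#' @param circuit an `emt_circuit`.
#' @param I_ext signal level (molecules), >= 0.
#' @return the modified circuit.
#' @export
set_signal <- function(circuit, I_ext) {
  if (!is.finite(I_ext) || I_ext < 0) stop("I_ext must be finite and >= 0")
  circuit$signal$value <- I_ext
  circuit
}

#' Remove a node and all its edges from a circuit
#'
#' Dropping KLF4 from the full circuit recovers the control core exactly: the
#' remaining nodes keep their parameters bit-for-bit.
#'
#' @param circuit an `emt_circuit`.
#' @param node node name to remove.
#' @return the reduced circuit.
#' @export
drop_node <- function(circuit, node) {
  if (!node %in% circuit$nodes$name) stop("unknown node: ", node)
  circuit$nodes <- circuit$nodes[circuit$nodes$name != node, , drop = FALSE]
  keep <- circuit$edges$source != node & circuit$edges$target != node
  circuit$edges <- circuit$edges[keep, , drop = FALSE]
  rownames(circuit$nodes) <- rownames(circuit$edges) <- NULL
  validate_circuit(circuit)
  circuit
}

VARIANT_EDGES <- list(
  klf4_self_activation = list(source = "KLF4", target = "KLF4", sign = "activation",
                              threshold = 30000, hill = 2, lambda = 2),
  slug_self_activation = list(source = "SLUG", target = "SLUG", sign = "activation",
                              threshold = 60000, hill = 2, lambda = 2),
  snail_self_inhibition = list(source = "SNAIL", target = "SNAIL", sign = "inhibition",
                               threshold = 200000, hill = 1, lambda = 0.1),
  zeb_self_activation = list(source = "ZEB", target = "ZEBm", sign = "activation",
                             threshold = 25000, hill = 2, lambda = 7.5)
)

#' Query or toggle optional self-regulation edges
#'
#' The circuit literature reports KLF4 self-activation, SLUG self-activation,
#' SNAIL self-inhibition and ZEB self-activation; the shipped configurations
#' enable the latter two (part of the core formulation) and leave the former
#' two off. `variant_flags` reports which optional edges are present;
#' `set_variant_flag` adds (with default kinetic parameters) or removes one.
#'
#' @param circuit an `emt_circuit`.
#' @param flag one of `"klf4_self_activation"`, `"slug_self_activation"`,
#'   `"snail_self_inhibition"`, `"zeb_self_activation"`.
#' @param enabled add (`TRUE`) or remove (`FALSE`) the edge.
#' @return `variant_flags`: named logical vector; `set_variant_flag`: the
#'   modified circuit.
#' @export
variant_flags <- function(circuit) {
  vapply(VARIANT_EDGES, function(e) {
    any(circuit$edges$source == e$source & circuit$edges$target == e$target &
          circuit$edges$sign == e$sign)
  }, logical(1))
}

#' @rdname variant_flags
#' @export
set_variant_flag <- function(circuit, flag, enabled) {
  e <- VARIANT_EDGES[[flag]]
  if (is.null(e)) stop("unknown variant flag: ", flag)
  present <- variant_flags(circuit)[[flag]]
  if (enabled && !present) {
    if (!all(c(e$source, e$target) %in% circuit$nodes$name)) {
      stop("variant edge endpoints absent from this circuit: ", flag)
    }
    circuit$edges <- rbind(circuit$edges, data.frame(
      source = e$source, target = e$target, sign = e$sign,
      mode = "transcriptional", threshold = e$threshold, hill = e$hill,
      lambda = e$lambda, stringsAsFactors = FALSE))
  } else if (!enabled && present) {
    drop <- circuit$edges$source == e$source & circuit$edges$target == e$target
    circuit$edges <- circuit$edges[!drop, , drop = FALSE]
  }
  validate_circuit(circuit)
  circuit
}

#' @export
print.emt_circuit <- function(x, ...) {
  cat("<emt_circuit> variant:", x$variant, "\n")
  cat(" nodes:", paste(x$nodes$name, collapse = ", "), "\n")
  cat(" edges:", nrow(x$edges),
      sprintf("(%d inhibitory, %d activating)",
              sum(x$edges$sign == "inhibition"), sum(x$edges$sign == "activation")), "\n")
  cat(" signal:", x$signal$node, "=", x$signal$value, "molecules\n")
  if (!is.null(x$mirna)) {
    cat(" microRNA module:", x$mirna$mir, "--|", x$mirna$mrna, "/", x$mirna$protein, "\n")
  }
  invisible(x)
}

# Compile an emt_circuit into the flat numeric encoding consumed by the C++
# kernels. Node order follows circuit$nodes.
compile_model <- function(circuit) {
  nd <- circuit$nodes; ed <- circuit$edges
  idx <- function(nm) match(nm, nd$name) - 1L
  m <- list(
    g = nd$g, k = nd$k, clamped = as.integer(nd$clamped),
    esrc = idx(ed$source), etgt = idx(ed$target),
    thr = ed$threshold, hill = ed$hill, lam = ed$lambda,
    has_mirna = !is.null(circuit$mirna)
  )
  if (m$has_mirna) {
    mm <- circuit$mirna
    m$mir <- idx(mm$mir); m$mrna <- idx(mm$mrna); m$prot <- idx(mm$protein)
    m$u0 <- mm$u0; m$l <- mm$l; m$gm <- mm$gamma_m; m$gu <- mm$gamma_u
  }
  m$node_names <- nd$name
  m
}

# --- named kinetic-parameter accessors ---------------------------------------
# Names follow "g:NODE", "k:NODE", "thr:SRC->TGT", "lam:SRC->TGT",
# "hill:SRC->TGT".

#' List the named kinetic parameters of a circuit
#' @param circuit an `emt_circuit`.
#' @param classes which parameter classes to list.
#' @return named numeric vector of parameter values.
#' @export
circuit_parameters <- function(circuit, classes = c("g", "k", "thr", "lam")) {
  nd <- circuit$nodes; ed <- circuit$edges
  out <- numeric(0)
  free <- !nd$clamped
  if ("g" %in% classes) out <- c(out, setNames(nd$g[free], paste0("g:", nd$name[free])))
  if ("k" %in% classes) out <- c(out, setNames(nd$k[free], paste0("k:", nd$name[free])))
  enm <- paste0(ed$source, "->", ed$target)
  if ("thr" %in% classes) out <- c(out, setNames(ed$threshold, paste0("thr:", enm)))
  if ("lam" %in% classes) out <- c(out, setNames(ed$lambda, paste0("lam:", enm)))
  if ("hill" %in% classes) out <- c(out, setNames(ed$hill, paste0("hill:", enm)))
  out
}

#' Get or set one named kinetic parameter
#' @param circuit an `emt_circuit`.
#' @param name parameter name, e.g. `"lam:KLF4->SNAIL"` or `"g:KLF4"`.
#' @param value replacement value (for `set_parameter`).
#' @return `get_parameter`: the value; `set_parameter`: the modified circuit.
#' @export
get_parameter <- function(circuit, name) {
  loc <- locate_parameter(circuit, name)
  if (loc$kind == "node") circuit$nodes[[loc$field]][loc$i]
  else circuit$edges[[loc$field]][loc$i]
}

#' @rdname get_parameter
#' @export
set_parameter <- function(circuit, name, value) {
  loc <- locate_parameter(circuit, name)
  if (loc$kind == "node") circuit$nodes[[loc$field]][loc$i] <- value
  else circuit$edges[[loc$field]][loc$i] <- value
  circuit
}

locate_parameter <- function(circuit, name) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed parameter name: ", name)
  cls <- parts[1]; key <- parts[2]
  if (cls %in% c("g", "k")) {
    i <- match(key, circuit$nodes$name)
    if (is.na(i)) stop("unknown node in parameter name: ", name)
    return(list(kind = "node", field = cls, i = i))
  }
  if (cls %in% c("thr", "lam", "hill")) {
    st <- strsplit(key, "->", fixed = TRUE)[[1]]
    if (length(st) != 2) stop("malformed edge parameter name: ", name)
    i <- which(circuit$edges$source == st[1] & circuit$edges$target == st[2])
    if (length(i) != 1) stop("unknown edge in parameter name: ", name)
    field <- c(thr = "threshold", lam = "lambda", hill = "hill")[[cls]]
    return(list(kind = "edge", field = field, i = i))
  }
  stop("unknown parameter class: ", cls)
}
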