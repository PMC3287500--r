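#' Reusable r-mesh components
#'
#' The building blocks of the constant-time dynamic-programming mesh: 1-bit
#' and n-bit max switches, the k x n adder/subtractor, and the n x (n+1)
#' on/off switch.  Each component is a mesh configuration with named input
#' and output port bindings; evaluating it means assigning the operand bits
#' to the input ports, performing one broadcasting step, and reading the
#' output ports.  Because the bus structure is independent of the operand
#' values, each component's bus network is resolved once and cached.
#'
#' @name components
NULL

# component template cache (bus networks resolved once per shape)
.component_cache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (!exists(key, envir = .component_cache, inherits = FALSE)) {
    assign(key, build(), envir = .component_cache)
  }
  get(key, envir = .component_cache)
}

new_component <- function(mesh, inputs, outputs, kind) {
  net <- resolve_buses(mesh)
  structure(list(mesh = mesh, net = net,
                 inputs = inputs, outputs = outputs, kind = kind,
                 inputs_idx = lapply(inputs, function(k) port_index(mesh, k)),
                 outputs_idx = if (length(outputs)) port_index(mesh, outputs) else integer(0)),
            class = "rmesh_component")
}

#' @export
pu_count.rmesh_component <- function(x, ...) pu_count(x$mesh)

#' @export
print.rmesh_component <- function(x, ...) {
  cat(sprintf("r-mesh component '%s': %d x %d grid, %d processing units\n",
              x$kind, x$mesh$dims[1], x$mesh$dims[2], pu_count(x)))
  cat("inputs: ", paste(names(x$inputs), collapse = ", "),
      "; output bits: ", length(x$outputs), "\n", sep = "")
  invisible(x)
}

#' Evaluate a component in one broadcasting step
#'
#' @param comp a component built by one of the `build_*` functions.
#' @param inputs named list of bit vectors, one entry per input binding of the
#'   component; each vector must match the binding's width.
#' @return integer bit vector read at the component's output ports.
#' @export
component_eval <- function(comp, inputs) {
  drives <- integer(0)
  idx <- integer(0)
  for (nm in names(comp$inputs)) {
    bind <- comp$inputs_idx[[nm]]
    bits <- inputs[[nm]]
    if (is.null(bits)) stop(sprintf("component_eval: missing input '%s'", nm))
    if (length(bits) != length(bind))
      stop(sprintf("component_eval: input '%s' has %d bits, binding expects %d",
                   nm, length(bits), length(bind)))
    drives <- c(drives, as.integer(bits))
    idx <- c(idx, bind)
  }
  .broadcast_read(comp$net, idx, drives, comp$outputs_idx)
}

# ---- 1-bit max switches ------------------------------------------------

#' Build the 1-bit max switches
#'
#' The 2-input switch is a single unit fusing \{NSEW\}: the max of two input
#' bits is their OR, which propagates over the fused bus.  The 4-input switch
#' uses 4 units configured \{NSW,E\}, \{NSE,W\}, \{NE,S,W\}, \{NSW,E\} on a
#' 2x2 grid; the four input ports and the output port share one bus, so the
#' output is the OR (= max) of the inputs.  A 3-input max is obtained by
#' loading a zero into one input port.
#'
#' @param n_inputs 2 or 4.
#' @return an `rmesh_component`.
#' @export
build_max_switch_1bit <- function(n_inputs = 4L) {
  if (n_inputs == 2L) {
    .cached("max2_1bit", function() {
      mesh <- mesh_config(1, 1, list("0,0" = "NSEW"))
      new_component(mesh,
                    inputs = list(in1 = "0,0,N", in2 = "0,0,W"),
                    outputs = "0,0,E", kind = "2-input 1-bit max switch")
    })
  } else if (n_inputs == 4L) {
    .cached("max4_1bit", function() {
      mesh <- mesh_config(2, 2, list("0,0" = "NSW|E", "0,1" = "NSE|W",
                                     "1,0" = "NE|S|W", "1,1" = "NSW|E"))
      new_component(mesh,
                    inputs = list(in1 = "0,0,N", in2 = "0,1,N",
                                  in3 = "0,0,W", in4 = "0,1,E"),
                    outputs = "1,1,S", kind = "4-input 1-bit max switch")
    })
  } else stop("build_max_switch_1bit: n_inputs must be 2 or 4")
}

#' Max of 2-4 input bits through the 1-bit switch
#'
#' @param inputs a vector of 2 to 4 bits.
#' @return the maximum (logical OR) bit.
#' @export
max_switch_1bit <- function(inputs) {
  inputs <- as.integer(inputs)
  stopifnot(length(inputs) >= 2L, length(inputs) <= 4L, all(inputs %in% 0:1))
  if (length(inputs) == 2L) {
    comp <- build_max_switch_1bit(2L)
    component_eval(comp, list(in1 = inputs[1L], in2 = inputs[2L]))
  } else {
    comp <- build_max_switch_1bit(4L)
    # unused ports load a zero value
    pad <- c(inputs, rep(0L, 4L - length(inputs)))
    component_eval(comp, list(in1 = pad[1L], in2 = pad[2L],
                              in3 = pad[3L], in4 = pad[4L]))
  }
}

# ---- n-bit max switch --------------------------------------------------

#' Build the n-bit max switch
#'
#' A stack of `w` 1-bit 4-input max switches, one per bit plane, placed on a
#' sparse grid so the per-bit blocks stay electrically isolated (4w
#' processing units in total).  For 1UN operands the bitwise OR of the bit
#' planes encodes the maximum of the values, because 1UN encodings are
#' prefixes of ones; the all-zero underflow marker contributes nothing and
#' therefore never beats a valid encoding.
#'
#' @param w operand bit width.
#' @return an `rmesh_component` with inputs `in1..in4`, each `w` bits.
#' @export
build_max_switch_nbit <- function(w) {
  w <- as.integer(w)
  stopifnot(w >= 1L)
  .cached(sprintf("maxn:%d", w), function() {
    c0 <- 3L * (seq_len(w) - 1L)
    parts <- stats::setNames(
      rep(c("NSW|E", "NSE|W", "NE|S|W", "NSW|E"), w),
      as.vector(rbind(paste0("0,", c0), paste0("0,", c0 + 1L),
                      paste0("1,", c0), paste0("1,", c0 + 1L))))
    inputs <- list(in1 = paste0("0,", c0, ",N"),
                   in2 = paste0("0,", c0 + 1L, ",N"),
                   in3 = paste0("0,", c0, ",W"),
                   in4 = paste0("0,", c0 + 1L, ",E"))
    outputs <- paste0("1,", c0 + 1L, ",S")
    mesh <- mesh_config(2, 3L * w - 1L, parts)
    new_component(mesh, inputs, outputs, kind = sprintf("%d-bit 4-input max switch", w))
  })
}

#' Max of 3-4 unary numbers on the n-bit switch
#'
#' @param inputs list of 3 or 4 1UN bit vectors (underflow patterns allowed),
#'   all of width `w`.
#' @param w bit width.
#' @return the 1UN encoding of the maximum input value; all-zero only if all
#'   inputs are underflow.
#' @export
max_switch_nbit <- function(inputs, w) {
  stopifnot(is.list(inputs), length(inputs) >= 3L, length(inputs) <= 4L)
  if (any(lengths(inputs) != w))
    stop("max_switch_nbit: width mismatch between operands and switch")
  for (u in inputs) if (!un_is_valid(u))
    stop("max_switch_nbit: operand is not a valid 1UN pattern")
  if (length(inputs) == 3L) inputs <- c(inputs, list(un_underflow(w)))
  comp <- build_max_switch_nbit(w)
  component_eval(comp, list(in1 = inputs[[1L]], in2 = inputs[[2L]],
                            in3 = inputs[[3L]], in4 = inputs[[4L]]))
}

# ---- adder / subtractor ------------------------------------------------

#' Build the k x n adder/subtractor
#'
#' The second operand `b` is a predefined magnitude (a score or gap cost),
#' left-shifted by one bit before feeding the West border so that its
#' zero-representing bit needs no row; rows for its trailing zeros are also
#' omitted, leaving `k = b` rows of `w` units.  Every unit in a row whose
#' West input is 1 fuses \{NE,SW\}, which diverts a bit entering at N one
#' column to the right on its way out S (a unary increment per row); the
#' West-border 1 itself surfaces at the South border as the new low bit.  For
#' subtraction the minuend enters the South border, the East border is fed no
#' signal, and the result is read (one-column-left-shifted per row) at the
#' North border; results that shift off the West edge underflow to all-zeros.
#'
#' @param b magnitude of the predefined operand (non-negative integer).
#' @param w bit width.
#' @return an `rmesh_component`; `b = 0` yields a rowless pass-through
#'   component handled behaviourally by [adder_subtractor()].
#' @export
build_adder_subtractor <- function(b, w) {
  b <- as.integer(b); w <- as.integer(w)
  stopifnot(b >= 1L, w >= 1L)
  .cached(sprintf("addsub:%d:%d", b, w), function() {
    keys <- paste0(rep(seq_len(b) - 1L, each = w), ",", rep(seq_len(w) - 1L, b))
    parts <- stats::setNames(rep("NE|SW", b * w), keys)
    mesh <- mesh_config(b, w, parts)
    new_component(
      mesh,
      inputs = list(north = sprintf("0,%d,N", seq_len(w) - 1L),
                    south = sprintf("%d,%d,S", b - 1L, seq_len(w) - 1L),
                    west  = sprintf("%d,0,W", seq_len(b) - 1L)),
      outputs = character(0),  # direction-dependent; see adder_subtractor()
      kind = sprintf("%d x %d adder/subtractor", b, w))
  })
}

#' Add or subtract a predefined magnitude in one broadcasting step
#'
#' @param a the first operand: a 1UN bit vector of width `w` (or a plain
#'   non-negative integer, which is encoded first).  The all-zero underflow
#'   pattern propagates unchanged through either operation, so a negative
#'   intermediate can never be resurrected downstream.
#' @param b magnitude of the predefined second operand.
#' @param mode `"add"` or `"subtract"`.
#' @param w bit width.
#' @return the 1UN result; `subtract` yields the all-zero underflow pattern
#'   when `a < b`.
#' @examples
#' un_decode(adder_subtractor(3, 3, "add", 8))      # 6, on a 3-row mesh
#' adder_subtractor(2, 5, "subtract", 8)            # all zeros (underflow)
#' @export
adder_subtractor <- function(a, b, mode = c("add", "subtract"), w) {
  mode <- match.arg(mode)
  w <- as.integer(w); b <- as.integer(b)
  stopifnot(b >= 0L)
  if (length(a) == 1L && !is.na(a) && a >= 0L) a <- un_encode(a, w)
  if (length(a) != w) stop("adder_subtractor: operand width mismatch")
  if (!un_is_valid(a)) stop("adder_subtractor: operand is not a valid 1UN pattern")
  if (un_is_underflow(a)) return(un_underflow(w))
  x <- un_decode(a)
  if (mode == "add" && x + b > w - 1L)
    stop(sprintf("adder_subtractor: capacity error, %d + %d exceeds width %d",
                 x, b, w))
  if (b == 0L) return(a)  # zero rows: the operand maps straight through
  comp <- build_adder_subtractor(b, w)
  west <- rep(1L, b)  # the left-shifted 1UN encoding of b is b ones
  if (mode == "add") {
    out <- .broadcast_read(comp$net,
                           c(comp$inputs_idx$north, comp$inputs_idx$west),
                           c(a, west), comp$inputs_idx$south)
  } else {
    out <- .broadcast_read(comp$net,
                           c(comp$inputs_idx$south, comp$inputs_idx$west),
                           c(a, west), comp$inputs_idx$north)
  }
  as.integer(out)
}

# ---- on/off switch -----------------------------------------------------

#' Build the n x (n+1) on/off switch
#'
#' Gates an n-bit 1UN value by a selector bit.  Bit `j` enters the North
#' border of column `j`, runs down to the main anti-diagonal cell (fusing
#' \{NE,S,W\}), then East along its row (cells below the anti-diagonal fuse
#' \{N,S,EW\}) to the last column.  When the selector is 1 the last-column
#' units pass East-West per row and the value appears on the East border;
#' when 0 they block and the output is all zeros.  The selector is known to
#' the sending cell (it is the affine gap tag), so the last column is
#' configured before the broadcast.
#'
#' @param w value bit width (the mesh is `w` rows by `w + 1` columns).
#' @param selector 0 or 1.
#' @return an `rmesh_component`.
#' @export
build_on_off_switch <- function(w, selector) {
  w <- as.integer(w); selector <- as.integer(selector)
  stopifnot(w >= 1L, selector %in% 0:1)
  .cached(sprintf("onoff:%d:%d", w, selector), function() {
    grid <- expand.grid(r = seq_len(w) - 1L, c = seq_len(w + 1L) - 1L)
    ps <- ifelse(grid$c == w, if (selector == 1L) "N|S|EW" else "NS|E|W",
          ifelse(grid$r == w - 1L - grid$c, "NE|S|W",
          ifelse(grid$r < w - 1L - grid$c, "NS|E|W", "N|S|EW")))
    parts <- stats::setNames(ps, paste0(grid$r, ",", grid$c))
    mesh <- mesh_config(w, w + 1L, parts)
    new_component(
      mesh,
      inputs = list(value = sprintf("0,%d,N", seq_len(w) - 1L),
                    selector = sprintf("0,%d,N", w)),
      outputs = sprintf("%d,%d,E", w - seq_len(w), w),
      kind = sprintf("%d x %d on/off switch", w, w + 1L))
  })
}

#' Gate a 1UN value by a selector bit
#'
#' @param value a 1UN bit vector of width `w` or a plain non-negative integer.
#' @param selector 1 passes the value through, 0 blocks it (all-zero output).
#' @param w bit width.
#' @return the gated 1UN bit vector.
#' @export
on_off_switch <- function(value, selector, w) {
  w <- as.integer(w)
  if (length(value) == 1L && !is.na(value) && value >= 0L) value <- un_encode(value, w)
  if (length(value) != w) stop("on_off_switch: value width mismatch")
  if (!un_is_valid(value)) stop("on_off_switch: value is not a valid 1UN pattern")
  comp <- build_on_off_switch(w, selector)
  as.integer(component_eval(comp, list(value = value, selector = as.integer(selector))))
}
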