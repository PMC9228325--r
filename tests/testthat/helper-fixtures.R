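# session-cached fixtures: the preset meshes are expensive to build, so the
# suite shares them across test files
.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

month12_build <- function(res = 64) {
  cached(paste0("m12_", res), build_heifer_mesh(shape_preset("month12"), res))
}

month12_small <- function() {
  cached("m12_small",
         build_heifer_mesh(shape_preset("month12"), 48, ground_truth = FALSE))
}

# headless variant of the month-12 shape (the torso moves to the body
# front when head and neck are absent, so the leg stations shift with it)
headless_shape <- function() {
  s <- shape_preset("month12")
  front <- s$head_length + s$neck_length
  s$head_radius <- 0
  s$neck_radius <- 0
  s$leg_stance_x <- s$leg_stance_x - front
  heifer3d:::validate_shape(s)
}

# drop all faces whose centroid satisfies a predicate (makes open meshes)
drop_faces_below <- function(mesh, z) {
  cz <- (mesh$vertices[mesh$faces[, 1], 3] + mesh$vertices[mesh$faces[, 2], 3] +
         mesh$vertices[mesh$faces[, 3], 3]) / 3
  mesh3t(mesh$vertices, mesh$faces[cz >= z, , drop = FALSE], validate = FALSE)
}

# Ramanujan's closed-form ellipse perimeter approximation (oracle)
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

rotation_z <- function(th) {
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# generic 3D rotation used for rigid-invariance checks
rotation_xyz <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3,
               byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, 3,
               byrow = TRUE)
  rz <- rotation_z(az)
  rz %*% ry %*% rx
}

# synthetic herd records with bw generated from a known linear law
herd_with_bw <- function(seed, n = 69, coefs = c(volume = 922.3),
                        intercept = -34.4, noise = 10) {
  herd <- simulate_herd(growth_params(), 5, seq(62, 605, length.out = 14),
                        seed = seed)
  tr <- herd$traits[seq_len(n), ]
  bw <- rep(intercept, n)
  for (p in names(coefs)) bw <- bw + coefs[[p]] * tr[[p]]
  tr$bw <- bw + heifer3d:::with_seed(seed + 7777, rnorm(n, 0, noise))
  tr
}
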