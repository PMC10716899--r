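Package: mdscript
Title: Declarative Scripting and Analysis Engine for Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless analysis core for molecular-dynamics trajectories
    built around a small declarative scripting language for atom selections
    and computed properties.  Selections carry contextual set semantics (the
    'in' keyword evaluates an operation once per context, e.g. per residue),
    and evaluated properties are temporal series, 1D distributions (including
    radial distribution functions), or 3D spatial distribution functions.
    Supporting machinery covers PDB/GRO/XYZ topology and trajectory input,
    csv/xvg/Gaussian-cube property exchange, periodic-boundary
    deperiodization and recentering, gyration-tensor shape anisotropy,
    selection growth, and Ramachandran backbone-dihedral densities with
    percentile-matched contour levels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
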