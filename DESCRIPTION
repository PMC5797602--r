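Package: complexion
Title: Contact, Ion-Atmosphere and Energetic Analysis of Protein-RNA Complexation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolbox for the association of an intrinsically
    disordered protein with an RNA polyanion in the presence of mono- and
    divalent counterions. Provides structure and trajectory containers with
    PDB/XYZ input, unit-cell symmetry expansion, named atom selections,
    residue-normalized protein-RNA coordination numbers with a PDB-survey
    selection filter, first-shell ion adsorption and salt-bridge charge
    accounting with half-charge splitting, radial distribution functions,
    inter-partner Lennard-Jones complexation energies, structural metrics
    (RMSD, radius of gyration, solvent-accessible surface area, assembly
    extent), a random-temperature Monte Carlo random-walk generator of
    non-overlapping initial configurations for disordered chains, and a
    synthetic-data module that plants every statistic the analyses recover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
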