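species_name,diagnostic_visibility,similar_species_in_region,notes
Suberites ficus,visible_with_difficulty,false,illustrative trait assignment
Ectopleura crocea,visible_with_difficulty,false,illustrative trait assignment
Pennaria disticha,easy_to_see,false,illustrative trait assignment
Obelia dichotoma,visible_with_difficulty,true,illustrative trait assignment
Ficopomatus enigmaticus,requires_dissection_or_molecular,false,genetic confirmation required for species-level identification
Anisolabis maritima,easy_to_see,false,illustrative trait assignment
Amphibalanus venustus,visible_with_difficulty,true,illustrative trait assignment
Balanus glandula,visible_with_difficulty,true,illustrative trait assignment
Megabalanus tintinnabulum,visible_with_difficulty,false,illustrative trait assignment
Ligia exotica,easy_to_see,true,illustrative trait assignment
Cymadusa filosa,visible_with_difficulty,true,illustrative trait assignment
Melita zeylanica,visible_with_difficulty,true,illustrative trait assignment
Carcinus maenas,easy_to_see,false,illustrative trait assignment
Bugulina flabellata,visible_with_difficulty,true,illustrative trait assignment
Virididentula dentata,visible_with_difficulty,true,illustrative trait assignment
Watersipora subtorquata,easy_to_see,true,illustrative trait assignment
Discinisca tenuis,visible_with_difficulty,false,illustrative trait assignment
Anteaeolidiella indica,easy_to_see,true,illustrative trait assignment
Myosotella myosotis,visible_with_difficulty,true,illustrative trait assignment
Polycera hedgpethi,easy_to_see,false,illustrative trait assignment
Tarebia granifera,easy_to_see,false,illustrative trait assignment
Thecacera pennigera,easy_to_see,false,illustrative trait assignment
Martesia striata,visible_with_difficulty,false,illustrative trait assignment
Mytilus galloprovincialis,easy_to_see,false,illustrative trait assignment
Semimytilus patagonicus,easy_to_see,true,illustrative trait assignment
Botryllus schlosseri,easy_to_see,true,illustrative trait assignment
Ciona robusta,easy_to_see,true,illustrative trait assignment
Clavelina lepadiformis,easy_to_see,true,illustrative trait assignment
Cystodytes dellechiajei,visible_with_difficulty,false,illustrative trait assignment
Styela plicata,requires_dissection_or_molecular,false,internal morphology required for species-level identification
Symplegma brakenhielmi,visible_with_difficulty,false,illustrative trait assignment
Codium fragile,requires_dissection_or_molecular,false,genetic confirmation required for species-level identification
Ulva lactuca,requires_dissection_or_molecular,false,genetic confirmation required for species-level identification
Asparagopsis armata,easy_to_see,true,illustrative trait assignment
Spartina maritima,easy_to_see,false,illustrative trait assignment
Stuckenia pectinata,visible_with_difficulty,false,illustrative trait assignment
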