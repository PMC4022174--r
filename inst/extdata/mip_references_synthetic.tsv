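ref_id	description	h2_pos	h5_pos	le1_pos	le2_pos	sequence
HsAQP1	synthetic aquaporin reference carrying the published HsAQP1 ar/R annotation (F56, H180, C189, R195)	56	180	189	195	GPHQRYTFKGNIGFKNMLLQPPPHAQKVMEQEGMFEEIEGRLCATPFANFNDDVVFSRDLERDSYKNSWGATDNPALAEADKCFVVYMGEVPMNSAFCTLSECEITGLDGRFVFTDSALTEKVNQPVTGTYGDAKVQETRIVGKALTKEVGDYRILALTFLELQITSLIIPNKYFADKFHSKPVGNPACTGDWDRECYTDGPGLLQIYGAIGVLSSLEQMPPVLKPEGIGYAGEELKALYFCTIAKVVTNKQECEGWDLSAKGKEHCILANKLSTFDPSQWMRIINRKFDTQPANEQMFSCELWS
EcGlpF	synthetic glyceroporin reference carrying the published EcGlpF ar/R annotation (W48, G191, F200, R205)	48	191	200	205	AHQPIYCATENMGFKNSSQVMTSECNFEEINARQCIVPFFNANDDVVWSRDLEFDMYSNSWGATDNPALAEADKSCFGTHIESKMVSAFCTLSECEITGNNRFFVFCDSALTEKVNQIDFMAESTLKVQNRHGYPWPGTLHTGDQKVQRIGTVVFALTKEVGDYRIMQLACLSDQVNSLITPRKFFADKFGSKPVGNPAFTGDWRECYTDGPALLQAIGANHCLSSLEQGALVLEPEGIMKATFELKALYFFTWARVLTTVTEMEGDDLDAKIPENMILADKLHAGEDSPGMRIMNSLFITAPANKGPVMDDLWS
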