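{"theta":0.0769610411361284,"theta_t":0,"seed":20170124,"per_snp":[{"rsid":"rs8000013","maf":0.1,"gamma":0.121799939113614,"alpha":0,"delta":0.0276141576423284,"Gamma":0.00937385012450078},{"rsid":"rs8000026","maf":0.138888888888889,"gamma":0.10667948691776,"alpha":0,"delta":0.0523858423576716,"Gamma":0.00821016438105877},{"rsid":"rs8000039","maf":0.177777777777778,"gamma":0.0974197686766892,"alpha":0,"delta":0.0177054837561912,"Gamma":0.00749752682459879},{"rsid":"rs8000052","maf":0.216666666666667,"gamma":0.0912658344969444,"alpha":0,"delta":0.0622945162438088,"Gamma":0.00702391364304242},{"rsid":"rs8000065","maf":0.255555555555556,"gamma":0.0870116953207547,"alpha":0,"delta":0.0375228315284657,"Gamma":0.00669651066290487},{"rsid":"rs8000078","maf":0.294444444444444,"gamma":0.0840408476522755,"alpha":0,"delta":0.0226598206992598,"Gamma":0.00646787113328188},{"rsid":"rs8000091","maf":0.333333333333333,"gamma":0.0820065142351329,"alpha":0,"delta":0.0474315054146029,"Gamma":0.00631130671548056},{"rsid":"rs8000104","maf":0.372222222222222,"gamma":0.0807023416152092,"alpha":0,"delta":0.0325684945853971,"Gamma":0.00621093623283},{"rsid":"rs8000117","maf":0.411111111111111,"gamma":0.0800030522033807,"alpha":0,"delta":0.0573401793007402,"Gamma":0.00615711819164021},{"rsid":"rs8000130","maf":0.45,"gamma":0.0798349204600772,"alpha":0,"delta":0.0424771684715343,"Gamma":0.00614417859762754}]}
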