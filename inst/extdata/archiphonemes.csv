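"language","phoneme","archiphoneme"
"English","p","|pb|"
"English","b","|pb|"
"English","t","|td|"
"English","d","|td|"
"English","k","|kg|"
"English","g","|kg|"
"English","tS","|tSdZ|"
"English","dZ","|tSdZ|"
"English","f","|fv|"
"English","v","|fv|"
"English","T","|TD|"
"English","D","|TD|"
"English","s","|sz|"
"English","z","|sz|"
"English","S","|SZ|"
"English","Z","|SZ|"
"English","h","|h|"
"English","m","|m|"
"English","n","|n|"
"English","N","|n|"
"English","r","|r|"
"English","l","|l|"
"English","j","|j|"
"English","w","|w|"
"English","I","|ie|"
"English","i","|ie|"
"English","e","|ie|"
"English","E","|ie|"
"English","i:","|ie|"
"English","eI","|ie|"
"English","I@","|ie|"
"English","e@","|ie|"
"English","jI","|ie|"
"English","ji","|ie|"
"English","je","|ie|"
"English","jE","|ie|"
"English","ji:","|ie|"
"English","jeI","|ie|"
"English","jI@","|ie|"
"English","je@","|ie|"
"English","rI","|ie|"
"English","ri","|ie|"
"English","re","|ie|"
"English","rE","|ie|"
"English","ri:","|ie|"
"English","reI","|ie|"
"English","rI@","|ie|"
"English","re@","|ie|"
"English","lI","|ie|"
"English","li","|ie|"
"English","le","|ie|"
"English","lE","|ie|"
"English","li:","|ie|"
"English","leI","|ie|"
"English","lI@","|ie|"
"English","le@","|ie|"
"English","{","|A|"
"English","A:","|A|"
"English","A","|A|"
"English","aI","|A|"
"English","aU","|A|"
"English","j{","|A|"
"English","jA:","|A|"
"English","jA","|A|"
"English","jaI","|A|"
"English","jaU","|A|"
"English","r{","|A|"
"English","rA:","|A|"
"English","rA","|A|"
"English","raI","|A|"
"English","raU","|A|"
"English","l{","|A|"
"English","lA:","|A|"
"English","lA","|A|"
"English","laI","|A|"
"English","laU","|A|"
"English","Q","|O|"
"English","O","|O|"
"English","O:","|O|"
"English","OI","|O|"
"English","jQ","|O|"
"English","jO","|O|"
"English","jO:","|O|"
"English","jOI","|O|"
"English","rQ","|O|"
"English","rO","|O|"
"English","rO:","|O|"
"English","rOI","|O|"
"English","lQ","|O|"
"English","lO","|O|"
"English","lO:","|O|"
"English","lOI","|O|"
"English","V","|UV|"
"English","U","|UV|"
"English","u","|UV|"
"English","u:","|UV|"
"English","U@","|UV|"
"English","jV","|UV|"
"English","jU","|UV|"
"English","ju","|UV|"
"English","ju:","|UV|"
"English","jU@","|UV|"
"English","rV","|UV|"
"English","rU","|UV|"
"English","ru","|UV|"
"English","ru:","|UV|"
"English","rU@","|UV|"
"English","lV","|UV|"
"English","lU","|UV|"
"English","lu","|UV|"
"English","lu:","|UV|"
"English","lU@","|UV|"
"English","3:","|&|"
"English","3`","|&|"
"English","@U","|&|"
"English","@","|&|"
"English","@`","|&|"
"English","j3:","|&|"
"English","j3`","|&|"
"English","j@U","|&|"
"English","j@","|&|"
"English","j@`","|&|"
"English","r3:","|&|"
"English","r3`","|&|"
"English","r@U","|&|"
"English","r@","|&|"
"English","r@`","|&|"
"English","l3:","|&|"
"English","l3`","|&|"
"English","l@U","|&|"
"English","l@","|&|"
"English","l@`","|&|"
"German","p","|pb|"
"German","b","|pb|"
"German","t","|td|"
"German","d","|td|"
"German","k","|kg|"
"German","g","|kg|"
"German","C","|kg|"
"German","x","|kg|"
"German","ts","|tSdZ|"
"German","tS","|tSdZ|"
"German","dZ","|tSdZ|"
"German","?","|?|"
"German","pf","|fv|"
"German","f","|fv|"
"German","v","|fv|"
"German","T","|TD|"
"German","D","|TD|"
"German","s","|sz|"
"German","z","|sz|"
"German","S","|SZ|"
"German","Z","|SZ|"
"German","h","|h|"
"German","m","|m|"
"German","n","|n|"
"German","N","|n|"
"German","R","|R|"
"German","l","|l|"
"German","j","|j|"
"German","I","|ie|"
"German","E","|ie|"
"German","i:","|ie|"
"German","e:","|ie|"
"German","E:","|ie|"
"German","jI","|ie|"
"German","jE","|ie|"
"German","ji:","|ie|"
"German","je:","|ie|"
"German","jE:","|ie|"
"German","rI","|ie|"
"German","rE","|ie|"
"German","ri:","|ie|"
"German","re:","|ie|"
"German","rE:","|ie|"
"German","lI","|ie|"
"German","lE","|ie|"
"German","li:","|ie|"
"German","le:","|ie|"
"German","lE:","|ie|"
"German","a","|A|"
"German","a:","|A|"
"German","aI","|A|"
"German","aU","|A|"
"German","ja","|A|"
"German","ja:","|A|"
"German","jaI","|A|"
"German","jaU","|A|"
"German","ra","|A|"
"German","ra:","|A|"
"German","raI","|A|"
"German","raU","|A|"
"German","la","|A|"
"German","la:","|A|"
"German","laI","|A|"
"German","laU","|A|"
"German","O","|O|"
"German","o:","|O|"
"German","OY","|O|"
"German","jO","|O|"
"German","jo:","|O|"
"German","jOY","|O|"
"German","rO","|O|"
"German","ro:","|O|"
"German","rOY","|O|"
"German","lO","|O|"
"German","lo:","|O|"
"German","lOY","|O|"
"German","Y","|UV|"
"German","U","|UV|"
"German","u:","|UV|"
"German","y:","|UV|"
"German","jY","|UV|"
"German","jU","|UV|"
"German","ju:","|UV|"
"German","jy:","|UV|"
"German","rY","|UV|"
"German","rU","|UV|"
"German","ru:","|UV|"
"German","ry:","|UV|"
"German","lY","|UV|"
"German","lU","|UV|"
"German","lu:","|UV|"
"German","ly:","|UV|"
"German","9","|&|"
"German","2:","|&|"
"German","@","|&|"
"German","6","|&|"
"German","j9","|&|"
"German","j2:","|&|"
"German","j@","|&|"
"German","j6","|&|"
"German","r9","|&|"
"German","r2:","|&|"
"German","r@","|&|"
"German","r6","|&|"
"German","l9","|&|"
"German","l2:","|&|"
"German","l@","|&|"
"German","l6","|&|"
"French","p","|pb|"
"French","b","|pb|"
"French","t","|td|"
"French","d","|td|"
"French","k","|kg|"
"French","g","|kg|"
"French","f","|fv|"
"French","v","|fv|"
"French","s","|sz|"
"French","z","|sz|"
"French","S","|SZ|"
"French","Z","|SZ|"
"French","h","|h|"
"French","m","|m|"
"French","n","|n|"
"French","N","|n|"
"French","J","|J|"
"French","w","|w|"
"French","i","|ie|"
"French","e","|ie|"
"French","E","|ie|"
"French","ji","|ie|"
"French","je","|ie|"
"French","jE","|ie|"
"French","ri","|ie|"
"French","re","|ie|"
"French","rE","|ie|"
"French","li","|ie|"
"French","le","|ie|"
"French","lE","|ie|"
"French","a","|A|"
"French","a~","|A|"
"French","A","|A|"
"French","ja","|A|"
"French","ja~","|A|"
"French","jA","|A|"
"French","ra","|A|"
"French","ra~","|A|"
"French","rA","|A|"
"French","la","|A|"
"French","la~","|A|"
"French","lA","|A|"
"French","o","|O|"
"French","o~","|O|"
"French","O","|O|"
"French","jo","|O|"
"French","jo~","|O|"
"French","jO","|O|"
"French","ro","|O|"
"French","ro~","|O|"
"French","rO","|O|"
"French","lo","|O|"
"French","lo~","|O|"
"French","lO","|O|"
"French","u","|UV|"
"French","y","|UV|"
"French","ju","|UV|"
"French","jy","|UV|"
"French","ru","|UV|"
"French","ry","|UV|"
"French","lu","|UV|"
"French","ly","|UV|"
"French","e~","|&|"
"French","2","|&|"
"French","9","|&|"
"French","9~","|&|"
"French","@","|&|"
"French","je~","|&|"
"French","j2","|&|"
"French","j9","|&|"
"French","j9~","|&|"
"French","j@","|&|"
"French","re~","|&|"
"French","r2","|&|"
"French","r9","|&|"
"French","r9~","|&|"
"French","r@","|&|"
"French","le~","|&|"
"French","l2","|&|"
"French","l9","|&|"
"French","l9~","|&|"
"French","l@","|&|"
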